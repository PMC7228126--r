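property,AAA,AAC,AAG,AAT,ACA,ACC,ACG,ACT,AGA,AGC,AGG,AGT,ATA,ATC,ATG,ATT,CAA,CAC,CAG,CAT,CCA,CCC,CCG,CCT,CGA,CGC,CGG,CGT,CTA,CTC,CTG,CTT,GAA,GAC,GAG,GAT,GCA,GCC,GCG,GCT,GGA,GGC,GGG,GGT,GTA,GTC,GTG,GTT,TAA,TAC,TAG,TAT,TCA,TCC,TCG,TCT,TGA,TGC,TGG,TGT,TTA,TTC,TTG,TTT
Bendability.DNase,37.211,28.493,22.322,18.27,26.973,17.786,24.605,11.787,17.947,19.955,15.695,5.18,18.587,21.116,24.173,27.849,12.729,23.49,29.052,23.676,28.381,25.624,22.741,18.771,26.71,23.283,27.635,11.978,20.62,11.38,17.359,33.847,17.525,23.811,21.529,13.804,17.129,24.883,11.231,26.615,13.608,26.079,21.988,32.724,16.668,12.993,29.314,16.084,14.333,16.621,16.911,28.661,21.618,17.474,13.073,26.957,27.762,20.687,22.231,20.793,21.005,23.575,17.128,24.676
Bendability.consensus,1.283,3.931,1.123,3.103,2.024,-1.834,0.63,0.033,-2.843,8.708,1.48,1.664,0.945,3.635,0.624,2.487,0.319,-0.063,3.47,3.239,0.407,6.497,-0.687,-0.054,3.591,0.08,0.428,2.114,-1.371,0.988,0.138,-0.357,-1.073,0.713,-0.901,-2.856,3.998,4.334,2.013,0.303,1.442,1.125,-0.033,2.649,-2.002,5.009,1.171,6.779,1.892,-0.258,-1.949,-1.251,3.321,0.01,-0.406,2,1.954,3.022,3.465,1.804,1.019,2.409,6.307,-2.385
Trinucleotide.GC.content,19.882,31.65,32.927,21.72,27.891,21.657,31.205,27.564,20.364,24.588,32.784,22.695,24.852,23.169,26.814,25.926,23.252,25.567,33.336,15.459,26.586,25.274,25.267,18.416,17.118,36.919,25.898,27.788,15.427,28.28,25.999,24.767,25.085,29.999,26.262,32.608,28.391,23.995,25.666,22.462,19.381,37.597,21.584,26.675,29.81,22.733,22.585,30.164,33.682,24.509,30.372,20.451,28.653,34.46,21.74,31.491,35.545,24.033,32.027,35.681,29.388,20.839,22.081,15.877
Nucleosome.positioning,-1.606,15.838,16.712,12.564,14.33,15.04,13.004,17.143,13.485,14.018,13.791,5.048,8.396,10.644,17.431,-1.686,11.001,11.363,2.24,13.589,10.139,10.04,2.978,11.529,7.788,19.059,6.414,11.723,8.502,13.721,0.569,12.808,7.71,-1.739,15.172,23.177,10.618,-1.976,17.077,24.893,15.691,19.645,8.932,6.826,9.346,16.015,2.986,10.842,11.081,9.375,9.785,5.35,6.477,13.039,8.297,13.164,5.742,2.921,16.762,16.514,11.432,14.08,11.898,15.782
Consensus.roll,-9.613,5.489,1.182,-1.336,-3.358,6.183,-4.713,-8.116,2.815,0.404,-5.102,-1.149,-6.584,6.324,-4.245,-1.164,-0.25,-8.978,9.326,-8.309,-7.431,-0.687,-3.902,-5.51,-1.94,-3.863,-4.388,7.392,0.61,1.686,-10.5,-1.692,-1.206,2.773,-9.541,-1.078,-11.064,-6.335,0.47,-0.839,-4.514,2.704,5.272,4.554,0.483,-0.768,0.956,-7.176,0.061,5.073,-4.417,-10.067,-8.731,-6.861,-1.827,7.657,-14.089,-3.183,-12.64,3.702,-5.703,1.373,-10.034,-6.186
Consensus.rigid,-0.35,4.944,13.37,-1.076,8.891,6.975,-3.559,-5.264,2.786,9.308,8.132,0.885,9.784,2.966,4.843,0.929,14.608,5.204,7.899,14.885,6.708,8.542,14.244,11.881,10.539,8.969,6.61,4.726,9.323,7.716,19.03,8.451,5.115,-6.239,11.521,14.375,-4.518,6.861,8.791,3.442,6.58,11.707,10.443,3.541,5.873,17.617,15.243,12.375,3.063,12.399,18.618,-2.625,4.68,-1.27,12.013,5.635,4.546,3.707,3.92,14.57,21.459,3.406,3.982,2.168
DNase.I,3.37,13.583,4.926,5.261,8.333,10.882,13.497,7.125,24.358,15.746,2.719,3.628,13.455,12.787,13.097,5.881,13.48,8.532,7.575,16.196,20.733,11.316,13.73,11.133,13.246,15.985,11.676,12.074,9.805,10.715,14.443,19.389,-4.996,27.506,15.196,20.643,16.84,12.023,8.763,18.518,15.847,8.618,-3.576,15.961,17.804,13.221,16.081,17.095,13.902,1.542,15.034,8.187,9.392,11.909,14.265,12.069,12.958,1.394,8.65,16.83,9.729,7.014,14.265,10.57
DNase.I.rigid,25.031,25.018,22.97,25.932,23.18,23.671,24.017,22.971,23.9,24.509,23.277,24.106,25.192,23.426,24.404,22.084,23.394,23.68,23.253,25.335,24.392,24.525,23.412,24.349,23.122,24.028,23.729,23.45,23.16,24.662,24.182,23.285,23.901,24.675,23.919,22.975,25.316,24.594,23.412,24.552,23.633,24.614,25.191,24.239,24.175,22.02,24.044,25.294,23.893,24.255,23.208,23.302,23.812,24.127,22.92,23.196,24.143,23.935,24.057,24.199,24.747,24.204,25.194,21.688
MW.daltons,25.907,26.235,30.613,34.467,27.582,24.888,25.211,30.356,28.852,31.948,25.531,26.113,28.635,27.909,24.826,28.017,20.857,28.17,27.989,19.56,26.288,23.99,25.351,29.055,33.525,29.901,31.477,29.799,31.344,27.234,29.416,26.689,21.325,25.573,23.805,20.441,31.957,33.199,32.13,26.165,22.101,28.417,25.616,31.156,28.483,24.767,22.512,22.634,29.597,30.111,27.008,29.252,24.129,26.591,27.501,21.459,27.67,26.056,31.434,35.654,26.339,32.825,26.407,33.16
Nucleosome,4.353,-7.253,13.267,-2.194,4.047,-5.293,1.136,15.347,6.884,1.041,11.587,13.516,14.54,-2.707,0.881,8.947,4.361,-4.82,5.986,6.724,-5.055,5.878,3.662,9.798,5.285,3.624,5.618,0.561,-3.784,9.985,17.152,-1.88,7.401,-4.507,5.187,2.385,-8.4,-2.943,3.584,10.959,1.434,2.56,6.069,-3.348,2.781,18.183,6.685,10.833,-0.794,8.349,8.675,0.493,7.918,0.606,-3.96,-7.706,10.747,4.491,0.675,4.397,3.182,11.255,6.99,9.233
Nucleosome.rigid,-9.8,8.59,-12.645,-4.559,-8.353,-0.004,0.692,0.368,3.347,-12.577,5.268,1.177,7.999,-4.695,-2.752,-3.926,0.524,-7.546,-6.96,-0.427,-6.41,-8.044,-3.205,0.984,3,-9.419,1.386,-6.117,-8.494,4.012,9.664,-7.217,4.13,-3.119,2.113,13.234,0.408,0.584,-10.022,2.038,-0.03,3.063,-2.014,-13.199,-1.359,1.587,-0.839,-1.605,7.19,-8.057,-0.063,-9.563,-1.905,3.829,0.591,1.44,-0.611,-0.944,-5.297,8.236,13.42,-4.542,2.023,4.338
Molecular.weight.kg,23.746,20.589,22.319,26.712,22.364,16.657,29.261,20.938,22.637,27.372,28.802,21.619,31.04,23.088,21.87,16.985,23.07,29.001,27.913,33.579,23.964,21.955,19.49,19.512,22.916,14.285,16.369,28.737,15.017,19.353,26.04,21.08,13.279,22.161,22.427,12.147,29.077,30.461,31.563,18.018,21.986,30.209,29.646,15.008,29.625,18.694,24.739,22.468,32.955,25.421,34.289,23.244,22.528,30.461,16.241,24.801,26.386,21.817,22.328,32.305,21.921,17.349,28.476,27.631
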