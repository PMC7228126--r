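property,AA,AC,AG,AT,CA,CC,CG,CT,GA,GC,GG,GT,TA,TC,TG,TT
Rise,18.298,20.066,20.936,9.832,26.062,7.353,19.885,6.053,6.112,29.39,16.883,30.287,18.717,11.174,13.711,25.569
Slide,12.983,11.16,9.447,3.059,7.703,16.009,14.92,12.225,8.584,10.183,7.875,9.39,4.617,3.443,14.13,16.415
Shift,28.006,28.595,28.345,25.959,30.131,30.098,27.189,30.538,28.894,27.906,30.484,27.566,24.657,24.553,34.555,28.103
Twist,9.383,4.959,2.356,10.189,-7.794,13.251,-5.085,9.437,9.08,4.766,10.137,-2.119,-3.321,11.737,2.72,-2.677
Roll,9.312,4.089,4.818,16.166,7.405,-2.313,14.109,5.328,2.917,9.934,0.321,8.014,7.998,13.667,9.856,12.448
Tilt,6.672,-0.279,3.266,6.19,2.719,2.737,6.17,5.601,11.831,0.852,5.781,7.674,8.081,9.313,8.622,3.908
Stacking.energy,4.51,12.61,-1.163,0.606,1.188,-1.295,-0.384,-9.077,3.132,5.561,-7.22,2.589,-2.157,-3.085,5.251,11.429
Enthalpy,25.002,22.783,24.895,25.74,25.033,25.556,26.739,24.666,25.479,25.251,24.928,25.553,25.224,24.446,24.039,25.232
Entropy,15.586,34.773,33.599,9.325,15.752,19.317,22.111,27.722,23.473,28.465,36.386,43.568,22.308,47.288,32.922,38.79
Free.energy,7.235,9.584,3.723,9.785,4.739,13.203,7.483,7.635,4.603,7.554,8.206,7.294,4.81,6.92,5.999,8.255
Melting.temperature,23.582,17.827,21.99,21.277,9.059,26.844,23.005,29.29,31.655,20.604,24.022,30.382,18.437,30.095,26.236,33.491
Bendability,10.016,11.167,7.711,11.516,9.833,9.974,9.234,9.571,8.766,12.651,9.81,10.291,11.224,8.028,10.848,11.545
Propeller.twist,20.691,12.139,23.595,26.238,14.969,14.248,14.965,29.37,14.282,12.793,14.41,22.917,18.895,15.06,10.834,13.899
Duplex.stability.disrupt,29.113,28.71,23.012,30.099,22.229,28.92,22.6,21.617,30.749,21.735,29.787,21.068,18.199,23.376,26.877,23.904
Duplex.stability.free,-8.859,4.42,-8.193,-7.012,0.083,-6.746,-5.449,3.302,-4.101,-7.015,4.261,0.358,-8.245,-5.526,-5.366,-7.081
Protein.induced.deformability,2.051,-17.341,-13.529,14.951,11.446,-5.34,18.081,21.332,22.324,2.688,15.821,8.73,2.856,21.194,21.855,-2.127
Protein.DNA.twist,24.169,25.852,26.463,25.953,25.018,26.371,30.171,25.122,27.192,30.042,26.931,26.37,26.764,28.358,27.915,27.848
Stabilising.energy.Z,0.68,4.39,-0.085,6.661,6.456,3.903,6.21,6.306,2.933,-0.505,8.186,1.749,4.961,-0.843,5.179,9.246
Breslauer.dG,27.531,24.211,23.62,26.263,15.721,30.512,15.793,24.155,17.686,17.052,28.673,9.99,26.593,21.036,16.907,13.307
Breslauer.dH,17.162,10.55,3.705,20.054,14.255,13.353,15.655,9.241,15.168,17.428,17.8,13.338,9.345,12.888,10.365,17.673
Breslauer.dS,19.139,24.741,17.672,26.289,7.774,-0.827,1.907,24.745,15.079,16.315,12.851,5.987,13.624,11.856,25.695,26.428
Hartman.trans.free.energy,1.895,-3.982,-0.103,0.571,0.732,3.337,-2.518,-3.602,1.92,-2.415,-2.856,2.483,4.888,-0.352,1.349,-1.888
Helix.twist,21.804,20.83,22.621,20.908,23.229,22.188,24.897,21.76,22.467,22.24,20.532,22.031,23.122,20.006,23.604,23.009
Ivanov.BA.transition,24.986,24.271,28.822,24.722,26.296,27.185,30.31,26.411,28.142,20.87,30.586,28.606,18.718,25.89,25.124,24.956
Lisser.BZ.transition,15.934,16.617,15.961,15.409,14.96,15.871,17.027,17.185,15.424,16.377,16.01,15.292,16.631,16.055,15.113,14.728
Polar.interaction,5.544,9.35,9.18,-2.503,17.83,11.279,14.153,6.07,2.134,16.557,18.833,13.959,15.033,15.314,17.779,19.986
SantaLucia.dG,2.734,6.035,-3.689,10.133,9.882,6.208,-5.322,7.047,10.689,14.652,12.255,7.062,1.636,4.124,12.297,-3.955
SantaLucia.dH,27.712,28.908,23.709,26.789,33.334,28.977,31.914,37.957,36.317,30.33,17.678,21.644,22.003,31.074,27.356,24.862
SantaLucia.dS,24.593,26.917,18.107,19.318,28.724,32.985,26.367,26.206,16.105,26.074,29.29,24.599,25.798,25.731,24.928,23.364
Sarai.flexibility,6.803,0.154,10.838,6.518,19.667,-3.364,0.239,4.183,8.061,-12.513,-1.17,-12.704,1.719,9.456,12.075,21.393
Stability,28.26,29.821,33.809,26.68,18.232,19.464,17.72,11.989,23.266,24.479,33.741,30.254,21.82,29.849,30.973,30.644
Watson.Crick.interaction,10.34,18.359,4.301,13.008,21.846,12.685,9.166,19.033,15.597,7.028,12.184,16.166,19.42,17.466,19.43,17.811
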