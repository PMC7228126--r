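#' Load a nucleotide property table
#'
#' The per-position encoder and the pseudo-composition encoders draw on 47
#' nucleotide properties: 3 binary chemical properties of single bases
#' (ring structure — purine 0 / pyrimidine 1; hydrogen bond — strong 0 /
#' weak 1; functional group — amino 0 / keto 1), 32 dinucleotide
#' physicochemical properties and 12 trinucleotide physicochemical
#' properties. Real-valued properties are standardized at load (mean 0,
#' sd 1 across the 16 or 64 k-mers); already-standardized input passes
#' through unchanged.
#'
#' The packaged dinucleotide/trinucleotide files are *synthetic* standardized
#' stand-ins with the same shape and naming as published property
#' compilations; substitute your own measured tables via the path arguments
#' for biological work. The chemical table is the exact 0/1 encoding.
#'
#' @param dinucleotide,trinucleotide,chemical Paths to CSV files with a
#'   `property` column followed by one column per k-mer. Defaults to the
#'   packaged tables.
#' @return A list of class `"property_table"` with matrices `chemical`
#'   (3 x 4), `dinucleotide` (32 x 16), `trinucleotide` (12 x 64).
#' @examples
#' pt <- load_property_table()
#' pt$chemical[, "A"]
#' rowMeans(pt$dinucleotide)  # ~0 after standardization
#' @export
load_property_table <- function(
    dinucleotide = system.file("extdata", "dinucleotide_properties_synthetic.csv",
                               package = "pseterm"),
    trinucleotide = system.file("extdata", "trinucleotide_properties_synthetic.csv",
                                package = "pseterm"),
    chemical = system.file("extdata", "chemical_properties.csv",
                           package = "pseterm")) {
  read_prop <- function(path, k) {
    df <- readr::read_csv(path, col_types = readr::cols(
      property = readr::col_character(), .default = readr::col_double()),
      progress = FALSE)
    km <- all_kmers(k)
    missing <- setdiff(km, names(df))
    if (length(missing)) {
      stop("property file ", path, " lacks k-mer columns: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(df[, km])
    rownames(m) <- df$property
    # standardize each property across its k-mers; no-op if already standard
    t(apply(m, 1, function(v) {
      s <- stats::sd(v)
      if (s < 1e-12) stop("constant property row in ", path, call. = FALSE)
      (v - mean(v)) / s
    }))
  }
  chem_df <- readr::read_csv(chemical, col_types = readr::cols(
    property = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  chem <- as.matrix(chem_df[, DNA_BASES])
  rownames(chem) <- chem_df$property
  if (!all(chem %in% c(0, 1))) {
    stop("chemical property values must be 0/1", call. = FALSE)
  }
  structure(list(chemical = chem,
                 dinucleotide = read_prop(dinucleotide, 2),
                 trinucleotide = read_prop(trinucleotide, 3)),
            class = "property_table")
}

# memoised default table
.pseterm_env <- new.env(parent = emptyenv())

default_property_table <- function() {
  if (is.null(.pseterm_env$props)) {
    .pseterm_env$props <- load_property_table()
  }
  .pseterm_env$props
}

# the six helical dinucleotide properties driving the pseudo components
PSEKNC_PROPS <- c("Rise", "Slide", "Shift", "Twist", "Roll", "Tilt")

#' @export
print.property_table <- function(x, ...) {
  cat("<property_table> 3 chemical + ", nrow(x$dinucleotide),
      " dinucleotide + ", nrow(x$trinucleotide),
      " trinucleotide properties (standardized)\n", sep = "")
  invisible(x)
}
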