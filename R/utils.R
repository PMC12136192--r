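# Internal helpers shared across modules.

#' @import data.table
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x <= 0 || x != as.integer(x))
    stop_cfg("'%s' must be a single positive integer (got %s)", name, paste(x, collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_cfg("'%s' must be a single value in [0, 1] (got %s)", name, paste(x, collapse = ","))
  as.numeric(x)
}

# -log10 with a guard so p in (0,1] never produces NaN
neg_log10 <- function(p) -log10(pmax(p, .Machine$double.xmin))

# Clamp a Gaussian upper-tail probability into (0, 1]
clamp_p <- function(p) pmin(pmax(p, 1e-300), 1)

utils::globalVariables(c(
  ".", "MARKER", "MARKER_A", "MARKER_B", "R2", "CHR", "POS", "PVALUE", "GENE",
  "SOURCE", "TARGET", "LEVEL", "START", "END", "NEG_LOG10_P", "MODULE", "TISSUE",
  "N_GENES", "N_MARKERS", "CHI", "NULL_MEAN", "NULL_SD", "Z", "P", "FDR", "KD",
  "GROUP", "DEGREE", "SUBNET_SIZE", "OVERLAP", "P_HYPERGEOM", "rank_", "BEST_P",
  "UNIT", "CLASS", "UNIT_SIZE", "CATALOG_SIZE", "BACKGROUND_SIZE", "FOLD",
  "PATHWAY", "SYSTEM", "REGION", "N_SYSTEMS", "MEDIAN_NEG_LOG10_FDR", "IS_KD",
  "RARE_LEVEL", "COMMON_NEG_LOG10_P", "RAW", "NORMALIZED", "block"
))
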