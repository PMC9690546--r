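#' @keywords internal
"_PACKAGE"

# Natural-numeric ordering of chromosome labels: labels that parse as numbers
# sort numerically first, the rest lexicographically after them. Labels are
# otherwise opaque text; no species-specific chromosome table is assumed.
natural_chrom_order <- function(labels) {
  u <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(u))
  is_num <- !is.na(num)
  ordered_u <- c(u[is_num][order(num[is_num])], sort(u[!is_num]))
  match(as.character(labels), ordered_u)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("angle_deg", "radius", "band"))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
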