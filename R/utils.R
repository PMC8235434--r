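# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# Every stochastic operation in the package funnels through this, which is
# what makes fixed-seed runs bit-identical.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "helixbind_config_error")
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_config <- function(msg) abort(msg, class = "helixbind_config_error")
stop_parse <- function(msg) abort(msg, class = "helixbind_parse_error")
stop_domain <- function(msg) abort(msg, class = "helixbind_domain_error")
stop_geometry <- function(msg) abort(msg, class = "helixbind_geometry_error")

assert_coords <- function(xyz, what = "coordinates") {
  if (!is.matrix(xyz) || ncol(xyz) != 3L) {
    stop_domain(sprintf("%s must be an n x 3 numeric matrix.", what))
  }
  if (!all(is.finite(xyz))) stop_domain(sprintf("%s contain non-finite values.", what))
  invisible(xyz)
}

# All-pairs distance matrix in Angstrom.
dist_matrix <- function(xyz) {
  as.matrix(stats::dist(xyz))
}
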