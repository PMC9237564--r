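#' @keywords internal
#' @useDynLib icnsync, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom sd median mad var aov lm coef anova
#'   p.adjust t.test cor.test fft quantile rpois predict manova
#' @importFrom utils head write.csv read.csv
"_PACKAGE"

# Run code under a temporary RNG state; restores .Random.seed afterwards so
# seeded generators never perturb the caller's stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seed derived from a master seed and a label.
# Keeps results independent across stages/participants while fully
# reproducible from one master seed. Stays below 2^31.
child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(charToRaw(lab), 64L)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

clip01 <- function(p, eps = 0) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop_invalid("analytic signal needs at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

inst_phase <- function(x) {
  if (stats::sd(x) == 0) stop_invalid("undefined phase: input has zero variance")
  Arg(analytic_signal(x))
}
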