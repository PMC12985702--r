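#' @useDynLib endobleed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile median sd qbeta plogis qnorm
#'   shapiro.test cor.test
#' @importFrom grDevices rgb2hsv
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

is_binary_mask <- function(m) {
  (is.logical(m) || all(m %in% c(0, 1))) && length(dim(m)) == 2L
}

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  if (!is_binary_mask(m)) stop("mask must be binary (logical or 0/1)", call. = FALSE)
  array(m != 0, dim = dim(m))
}

# HSV (hue in half-degrees [0,180), S and V on 0-255) -> RGB on 0-255.
# Standard hexcone formula; vectorised.
hsv_to_rgb255 <- function(h_half, s, v) {
  h_deg <- (h_half %% 180) * 2
  s1 <- s / 255; v1 <- v / 255
  c <- v1 * s1
  hp <- h_deg / 60
  x <- c * (1 - abs(hp %% 2 - 1))
  m <- v1 - c
  r <- g <- b <- numeric(length(h_deg))
  i <- floor(hp) %% 6
  r <- ifelse(i == 0 | i == 5, c, ifelse(i == 1 | i == 4, x, 0))
  g <- ifelse(i == 1 | i == 2, c, ifelse(i == 0 | i == 3, x, 0))
  b <- ifelse(i == 3 | i == 4, c, ifelse(i == 2 | i == 5, x, 0))
  cbind(r = (r + m) * 255, g = (g + m) * 255, b = (b + m) * 255)
}

# md5 of an R object via its canonical JSON form (configs/manifests only).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

stop_endobleed <- function(msg, class) {
  stop(structure(class = c(class, "endobleed_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
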