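#' Derive a reproducible stage seed from a master seed
#'
#' Stage seeds are derived by a stable polynomial hash of the stage label and
#' item name, so per-term seeds do not depend on the order in which terms are
#' visited and every source of randomness in a run traces back to one master
#' seed.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. \code{"term_preservation"}).
#' @param name character item name (e.g. a GO term name); optional.
#' @return A single integer in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(master, stage, name = "") {
  mod <- 2147483647  # 2^31 - 1; products stay far below 2^53 in doubles
  h <- 0
  for (b in utf8ToInt(paste0(stage, "\r", name))) {
    h <- (h * 31 + b) %% mod
  }
  as.integer((abs(as.numeric(master)) %% mod * 48271 + h) %% mod)
}

# row-standardize a genes x samples matrix; zero-variance rows -> all zero.
# NAs are imputed to the row mean (i.e. 0 after centering).
standardize_rows <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2, na.rm = TRUE) / (pmax(rowSums(!is.na(xc)), 2) - 1))
  ok <- is.finite(s) & s > 0
  xc[ok, ] <- xc[ok, , drop = FALSE] / s[ok]
  xc[!ok, ] <- 0
  xc[is.na(xc)] <- 0
  attr(xc, "zero_variance") <- rownames(x)[!ok]
  xc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
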