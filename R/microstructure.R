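# Microstructural profile covariance (MPC): depth-wise intensity profiles
# are corrected for the midsurface y-coordinate, standardized, and
# correlated between regions partialling out the cortex-wide mean profile.

#' Residualize intensity profiles against the midsurface y-coordinate
#'
#' Each depth column is regressed on y and replaced by its standardized
#' residuals (zero mean, unit variance per depth). With a constant y the
#' correction is skipped (profiles are only standardized) and the result is
#' flagged.
#'
#' @param profiles regions x depths intensity matrix (>= 3 regions).
#' @param y midsurface y-coordinate per region.
#' @return Standardized residual matrix with attribute `y_corrected`.
#' @export
residualize_profiles <- function(profiles, y) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stop_param("need at least 3 regions")
  if (length(y) != nrow(profiles))
    stop_param("y must have one value per region")
  corrected <- TRUE
  if (sd(y) == 0) {
    warning("constant y-coordinate: correction skipped")
    res <- scale(profiles, center = TRUE, scale = FALSE)
    corrected <- FALSE
  } else {
    res <- apply(profiles, 2, function(col) resid(lm(col ~ y)))
  }
  out <- apply(res, 2, function(col) {
    s <- sd(col)
    if (s <= 1e-10) col else (col - mean(col)) / s
  })
  dimnames(out) <- dimnames(profiles)
  attr(out, "y_corrected") <- corrected
  out
}

#' Microstructural profile covariance matrix
#'
#' Partial correlation between every pair of regions' depth profiles,
#' controlling for the cortex-wide mean profile. When the input has been
#' standardized per depth across regions the mean profile is null — that
#' standardization already removed the cortex-wide component — and the
#' partial correlation reduces to the plain profile correlation.
#' Non-positive correlations
#' are thresholded to 0 in the raw channel; positive correlations are mapped
#' through `log(r / (1 - r))` in the transformed channel, with non-positive
#' entries floored to the minimum transformed value so the matrix stays
#' dense for curve code. Both channels are returned since the exact log
#' variant differs between published pipelines.
#'
#' @param resid_profiles standardized residual profiles (regions x depths),
#'   e.g. from [residualize_profiles()].
#' @return list of class `mpc`: `r` (partial correlations, non-positive
#'   values set to 0, NA diagonal), `mpc` (log-transformed channel),
#'   `floor` (value used for non-positive correlations), `undefined`
#'   (regions with zero residual variance).
#' @export
mpc_matrix <- function(resid_profiles) {
  p <- as.matrix(resid_profiles)
  if (nrow(p) < 3) stop_param("need at least 3 regions")
  m <- colMeans(p)
  rv <- apply(p, 1, sd)
  undefined <- rv <= 1e-10
  C <- suppressWarnings(cor(t(p)))
  # depth-standardized inputs have a null mean profile: the standardization
  # already removed the cortex-wide component, so partialling is a no-op
  if (sd(m) > 1e-8) {
    cm <- suppressWarnings(as.numeric(cor(t(p), m)))
  } else {
    cm <- rep(0, nrow(p))
  }
  den <- sqrt(outer(1 - cm^2, 1 - cm^2))
  pc <- (C - outer(cm, cm)) / den
  pc[undefined, ] <- NA_real_
  pc[, undefined] <- NA_real_
  diag(pc) <- NA_real_
  pc <- pmin(pc, 1 - 1e-12)

  raw <- pc
  raw[!is.na(raw) & raw <= 0] <- 0
  trans <- pc
  pos <- !is.na(pc) & pc > 0
  trans[pos] <- log(pc[pos] / (1 - pc[pos]))
  floor_val <- if (any(pos)) min(trans[pos]) else 0
  trans[!is.na(pc) & pc <= 0] <- floor_val
  structure(list(r = raw, mpc = trans, floor = floor_val,
                 undefined = which(undefined)),
            class = "mpc")
}

#' Extract MPC values for a set of edges
#'
#' @param mpc an `mpc` object.
#' @param edges data.frame with region indices `i`, `j`.
#' @param channel `"mpc"` (log-transformed) or `"r"` (raw).
#' @return Numeric vector of edge values.
#' @export
mpc_edge_values <- function(mpc, edges, channel = c("mpc", "r")) {
  channel <- match.arg(channel)
  mpc[[channel]][cbind(edges$i, edges$j)]
}
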