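#' Spearman rank correlation between a density and a rate track
#'
#' Average ranks are assigned to ties and rho is the Pearson correlation of
#' the rank vectors. For n >= 10 the p-value uses the t approximation with
#' n - 2 degrees of freedom; for n < 10 it is the exact two-sided
#' permutation p over all n! orderings. Pairs with a missing value on
#' either side are dropped first. Constant input on either side leaves rho
#' undefined: NA is returned with a warning.
#'
#' @param density numeric vector (per-bin motif density).
#' @param rate numeric vector of the same length (per-bin rate).
#' @param pFloor smallest reportable p-value (default 1e-300), used when
#'   the test statistic is unbounded (|rho| = 1).
#' @return a list with elements rho, p, n.
#' @examples
#' spearmanAssoc(c(1, 2, 2, 3), c(1, 2, 3, 4))$rho  # 4.5/sqrt(22.5)
#' @export
spearmanAssoc <- function(density, rate, pFloor = 1e-300) {
  if (length(density) != length(rate)) stop("inputs must have equal length")
  ok <- !is.na(density) & !is.na(rate)
  x <- density[ok]; y <- rate[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 non-missing pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input: Spearman rho undefined, reported as missing")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  rho <- sum(cx * cy) / denom
  if (n >= 10L) {
    if (abs(rho) >= 1) {
      p <- pFloor
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      p <- max(p, pFloor)
    }
  } else {
    perms <- .allPerms(n)
    rhoPerm <- as.numeric(matrix(cy[perms], nrow(perms)) %*% cx) / denom
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9 in practice)
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(rep.int(i, nrow(sub)), sub + (sub >= i))
  }))
}

#' Ordinary least squares of rate on density
#'
#' Fits \code{rate ~ density} by OLS (via [stats::lm()]) and reports the
#' slope, intercept, two-sided slope t-test p-value and R-squared. An
#' exactly collinear (zero-residual) fit has an unbounded t statistic: its
#' p-value is reported as the floor constant \code{pFloor} rather than 0.
#' Constant density leaves the slope undefined (NA with a warning).
#'
#' @param density numeric predictor vector.
#' @param rate numeric response vector.
#' @param pFloor smallest reportable p (default 1e-300).
#' @return a list with slope, intercept, p, r_squared, n.
#' @export
olsFit <- function(density, rate, pFloor = 1e-300) {
  if (length(density) != length(rate)) stop("inputs must have equal length")
  ok <- !is.na(density) & !is.na(rate)
  x <- density[ok]; y <- rate[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 non-missing pairs")
  if (length(unique(x)) < 2L) {
    warning("constant density: OLS slope undefined, reported as missing")
    return(list(slope = NA_real_, intercept = NA_real_, p = NA_real_,
                r_squared = NA_real_, n = n))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on numerically perfect fits; that case is handled below
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- sm$r.squared
  p <- stats::coef(sm)[2L, 4L]
  tss <- sum((y - mean(y))^2)
  if (tss > 0 && sum(stats::resid(fit)^2) <= 1e-12 * tss) {
    # numerically perfect line: below the machine-reportable floor
    p <- pFloor
    r2 <- 1
  }
  if (!is.finite(p) || p < pFloor) p <- pFloor
  list(slope = slope, intercept = intercept, p = p, r_squared = r2, n = n)
}

#' Motif x stratum x scale association grid
#'
#' For every motif density track and every smoothing scale of the map,
#' computes per-chromosome Spearman and OLS associations between per-bin
#' motif density and recombination rate, plus a pooled "genome" stratum
#' formed by concatenating the per-chromosome bin vectors whenever at least
#' two chromosomes are present. Bins with a missing rate are dropped
#' pairwise inside each test. Mismatched binning between a density track
#' and a map is a contract error, never silently resampled.
#'
#' @param mapsByScale named list of [RecombinationMap-class] objects, one
#'   per smoothing scale, names giving the scale in kb (e.g. "1", "5").
#' @param densityTracks a [DensityTrack-class] or named list of them (one
#'   per motif).
#' @param bhColumn add a Benjamini-Hochberg adjusted column \code{rho_q}
#'   across all grid cells (default TRUE); raw p-values stay untouched.
#' @return a tidy data frame (motif, stratum, scale_kb, n, rho, rho_p,
#'   slope, intercept, slope_p, r2[, rho_q]).
#' @export
associationGrid <- function(mapsByScale, densityTracks, bhColumn = TRUE) {
  if (is(mapsByScale, "RecombinationMap"))
    mapsByScale <- list("1" = mapsByScale)
  if (is.null(names(mapsByScale)))
    stop("mapsByScale must be a named list (names = scale in kb)")
  if (is(densityTracks, "DensityTrack"))
    densityTracks <- setNames(list(densityTracks),
                              motifName(densityTracks))
  rows <- list()
  for (motif in names(densityTracks)) {
    track <- densityTracks[[motif]]
    dv <- densityValues(track)
    for (scale in names(mapsByScale)) {
      map <- mapsByScale[[scale]]
      if (binSize(map) != binSize(track))
        stop("mismatched binning: map at ", binSize(map), " bp vs density at ",
             binSize(track), " bp (rebin first)")
      chroms <- intersect(chromNames(map), chromNames(track))
      if (length(chroms) == 0L) stop("no shared chromosomes")
      rv <- rateValues(map)
      for (chr in chroms) {
        if (length(dv[[chr]]) != length(rv[[chr]]))
          stop("bin count mismatch on ", chr)
        rows[[length(rows) + 1L]] <-
          .assocRow(motif, chr, scale, dv[[chr]], rv[[chr]])
      }
      if (length(chroms) >= 2L) {
        rows[[length(rows) + 1L]] <-
          .assocRow(motif, "genome", scale,
                    unlist(dv[chroms], use.names = FALSE),
                    unlist(rv[chroms], use.names = FALSE))
      }
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  if (bhColumn) grid$rho_q <- stats::p.adjust(grid$rho_p, method = "BH")
  grid
}

.assocRow <- function(motif, stratum, scale, d, r) {
  sp <- suppressWarnings(spearmanAssoc(d, r))
  ols <- suppressWarnings(olsFit(d, r))
  data.frame(motif = motif, stratum = stratum,
             scale_kb = as.numeric(scale), n = sp$n,
             rho = sp$rho, rho_p = sp$p,
             slope = ols$slope, intercept = ols$intercept,
             slope_p = ols$p, r2 = ols$r_squared)
}

#' Bar plot of an association grid
#'
#' Bars show Spearman's rho per stratum, faceted by smoothing scale, with
#' transparency tracking the p-value (more opaque = more significant).
#' Requires ggplot2.
#'
#' @param grid a data frame from [associationGrid()].
#' @return a ggplot object.
#' @export
plotAssociationGrid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotAssociationGrid needs the ggplot2 package")
  grid$alpha <- pmin(1, pmax(0.2, -log10(pmax(grid$rho_p, 1e-16)) / 8))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[["stratum"]],
                                     y = .data[["rho"]],
                                     fill = .data[["motif"]],
                                     alpha = .data[["alpha"]])) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~scale_kb) +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = NULL, y = "Spearman's rho") +
    ggplot2::theme_minimal()
}
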