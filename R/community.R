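.bb_midpoints <- c("r" = 0.1, "+" = 0.5, "1" = 2.5, "2" = 15, "2a" = 10,
                   "2b" = 20.5, "3" = 37.5, "4" = 62.5, "5" = 87.5)

#' Convert Braun-Blanquet cover-abundance classes to percent cover
#'
#' Class midpoints: r = 0.1, + = 0.5, 1 = 2.5, 2 = 15 (2a = 10, 2b = 20.5),
#' 3 = 37.5, 4 = 62.5, 5 = 87.5 percent.
#'
#' @param class_label Character vector of class labels.
#' @return Numeric percent cover.
#' @export
braun_blanquet_to_cover <- function(class_label) {
  class_label <- as.character(class_label)
  bad <- setdiff(unique(class_label), names(.bb_midpoints))
  if (length(bad))
    stop("unknown Braun-Blanquet class(es): ", paste(bad, collapse = ", "))
  unname(.bb_midpoints[class_label])
}

#' Convert percent cover to Braun-Blanquet classes
#'
#' Inverse of [braun_blanquet_to_cover()] by interval (using the 2a/2b
#' subdivision): (0, 0.3] = r, (0.3, 1] = +, (1, 5] = 1, (5, 15] = 2a,
#' (15, 25] = 2b, (25, 50] = 3, (50, 75] = 4, (75, 100] = 5; zero cover maps
#' to `NA` (absent).
#'
#' @param percent Numeric percent cover in `[0, 100]`.
#' @return Character vector of class labels (`NA` for zeros).
#' @export
cover_to_braun_blanquet <- function(percent) {
  stopifnot(all(percent >= 0 & percent <= 100))
  breaks <- c(0, 0.3, 1, 5, 15, 25, 50, 75, 100)
  labels <- c("r", "+", "1", "2a", "2b", "3", "4", "5")
  out <- as.character(cut(percent, breaks, labels))
  out[percent == 0] <- NA_character_
  out
}

#' Abundance-weighted mean indicator value
#'
#' The community-level light indicator: `sum(a_i * L_i) / sum(a_i)` over the
#' species that have both a positive abundance and an indicator value;
#' species lacking an indicator value are excluded from both sums.
#'
#' @param abundances Numeric vector of abundances (e.g. percent cover).
#' @param indicator_values Numeric indicator values (may contain `NA`).
#' @return The weighted mean.
#' @export
weighted_indicator_mean <- function(abundances, indicator_values) {
  stopifnot(length(abundances) == length(indicator_values))
  ok <- !is.na(indicator_values) & !is.na(abundances) & abundances > 0
  if (!any(ok))
    stop("no species with positive abundance and an indicator value")
  sum(abundances[ok] * indicator_values[ok]) / sum(abundances[ok])
}

#' Linear regression of a community response on a light proxy
#'
#' Ordinary least squares of e.g. the plot-level weighted light indicator on
#' the plot-mean log-transformed proxy.
#'
#' @param response Numeric response per plot.
#' @param proxy Numeric predictor per plot (typically a log-scale mean).
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
proxy_regression <- function(response, proxy) {
  stopifnot(length(response) == length(proxy))
  if (length(response) < 3) stop("need at least 3 plots")
  if (sd(proxy) == 0) stop("proxy is constant across plots")
  fit <- lm(response ~ proxy)
  s <- summary(fit)
  p <- if (nrow(s$coefficients) > 1) s$coefficients[2, 4] else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, p_value = p, n = length(response))
}

#' Simpson pairwise dissimilarity (turnover component of beta diversity)
#'
#' `beta_sim(i, j) = min(b, c) / (a + min(b, c))` where `a` is the number of
#' shared species and `b`, `c` the numbers unique to each plot. Computed on
#' presence/absence; nested plot pairs score 0 (no turnover). Pairs with
#' `a + min(b, c) = 0` are defined as 0.
#'
#' @param comm Plot x species matrix (abundances or presences; any positive
#'   value counts as presence). Needs at least 2 plots.
#' @return Symmetric plot x plot matrix in `[0, 1]` with zero diagonal.
#' @export
simpson_dissimilarity <- function(comm) {
  comm <- as.matrix(comm)
  if (nrow(comm) < 2) stop("need at least 2 plots")
  p <- (comm > 0) * 1
  a <- tcrossprod(p)                # shared species
  s <- rowSums(p)
  b <- matrix(s, nrow(p), nrow(p)) - a          # unique to row plot
  cc <- t(b)                                    # unique to column plot
  mn <- pmin(b, cc)
  denom <- a + mn
  d <- ifelse(denom > 0, mn / denom, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(comm), rownames(comm))
  d
}

#' Distance-based redundancy analysis (db-RDA)
#'
#' Principal-coordinate decomposition of the dissimilarity matrix followed by
#' redundancy analysis of the real (positive-eigenvalue) axes on the
#' covariates, via [vegan::capscale()]. Negative eigenvalues are dropped and
#' the R-squared denominator is the positive-eigenvalue inertia. Collinear
#' covariate columns are dropped with a warning; the adjusted R-squared
#' (Ezekiel) uses the number of retained columns.
#'
#' @param D Symmetric dissimilarity matrix (or `dist`).
#' @param X Data frame of covariates (rows aligned with `D`).
#' @return A list with `r_squared`, `adj_r_squared`, `n`, `p` (retained
#'   covariates), and the fitted capscale `model`.
#' @export
db_rda <- function(D, X) {
  D <- stats::as.dist(D)
  n <- attr(D, "Size")
  X <- as.data.frame(X)
  names(X) <- make.names(names(X), unique = TRUE)
  if (nrow(X) != n) stop("covariate rows must match the dissimilarity matrix")
  mm <- stats::model.matrix(~ ., data = X)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    drop_cols <- colnames(mm)[-qr_$pivot[seq_len(qr_$rank)]]
    warning("dropping collinear covariate(s): ",
            paste(drop_cols, collapse = ", "))
    keep <- intersect(colnames(X),
                      colnames(mm)[qr_$pivot[seq_len(qr_$rank)]])
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  mod <- vegan::capscale(D ~ ., data = X)
  # denominator: positive-eigenvalue (real) inertia only; capscale's tot.chi
  # would include the imaginary part
  ca <- if (!is.null(mod$CA)) mod$CA$tot.chi else 0
  r2 <- mod$CCA$tot.chi / (mod$CCA$tot.chi + ca)
  adj <- if (n > p + 1) adjusted_r2(r2, n, p) else NA_real_
  list(r_squared = r2, adj_r_squared = adj, n = n, p = p, model = mod)
}

#' Ezekiel adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`.
#'
#' @param r_squared Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number of predictors.
#' @return Adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r_squared, n, p) {
  if (n <= p + 1) stop("adjusted R-squared needs n > p + 1")
  1 - (1 - r_squared) * (n - 1) / (n - p - 1)
}

#' Variation partitioning of a dissimilarity matrix across three groups
#'
#' Fits db-RDA models for the seven non-empty unions of the three covariate
#' groups, converts each to an adjusted R-squared, and solves the
#' inclusion-exclusion system for the seven disjoint fractions (three
#' independent, three pairwise-shared, one triple-shared) plus the residual.
#' Raw fractions sum to 1 with the residual by construction; the reporting
#' view floors negative fractions at zero (they arise when a group explains
#' less than random covariates would).
#'
#' @param D Symmetric dissimilarity matrix (or `dist`).
#' @param light,climate,soil Data frames of covariates for the three groups.
#' @return A `varpart_result`: list with `adj_r2` (the 7 model values),
#'   `fractions` (raw, named, incl. `residual`), `fractions_display`
#'   (negatives floored), `n`.
#' @export
variation_partition <- function(D, light, climate, soil) {
  groups <- list(light = as.data.frame(light),
                 climate = as.data.frame(climate),
                 soil = as.data.frame(soil))
  if (any(vapply(groups, ncol, 0L) == 0)) stop("all groups must be non-empty")
  union_of <- function(which) {
    df <- do.call(cbind, unname(groups[which]))
    names(df) <- make.names(names(df), unique = TRUE)
    df
  }
  fit <- function(which) db_rda(D, union_of(which))$adj_r_squared
  r <- c(A = fit("light"), B = fit("climate"), C = fit("soil"),
         AB = fit(c("light", "climate")), AC = fit(c("light", "soil")),
         BC = fit(c("climate", "soil")),
         ABC = fit(c("light", "climate", "soil")))
  if (any(is.na(r))) stop("too few plots for the full model")
  # unknowns: a, b, c (independent), d = light&climate, e = climate&soil,
  # f = light&soil, g = all three
  M <- rbind(
    A   = c(1, 0, 0, 1, 0, 1, 1),
    B   = c(0, 1, 0, 1, 1, 0, 1),
    C   = c(0, 0, 1, 0, 1, 1, 1),
    AB  = c(1, 1, 0, 1, 1, 1, 1),
    AC  = c(1, 0, 1, 1, 1, 1, 1),
    BC  = c(0, 1, 1, 1, 1, 1, 1),
    ABC = c(1, 1, 1, 1, 1, 1, 1))
  x <- solve(M, r)
  fr <- c(light = x[[1]], climate = x[[2]], soil = x[[3]],
          light_climate = x[[4]], climate_soil = x[[5]],
          light_soil = x[[6]], all_shared = x[[7]],
          residual = 1 - r[["ABC"]])
  disp <- fr
  disp[seq_len(7)] <- pmax(disp[seq_len(7)], 0)
  structure(list(adj_r2 = r, fractions = fr, fractions_display = disp,
                 n = attr(stats::as.dist(D), "Size")),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R-squared fractions)\n")
  cat(sprintf("  full model: %.3f   residual: %.3f\n",
              x$adj_r2[["ABC"]], x$fractions[["residual"]]))
  lab <- c(light = "light (independent)",
           climate = "climate (independent)",
           soil = "soil (independent)",
           light_climate = "light & climate",
           climate_soil = "climate & soil",
           light_soil = "light & soil",
           all_shared = "shared by all")
  for (nm in names(lab)) {
    raw <- x$fractions[[nm]]
    cat(sprintf("  %-22s %6.3f%s\n", lab[[nm]], max(raw, 0),
                if (raw < 0) sprintf("  (raw %.3f, reported as 0)", raw) else ""))
  }
  invisible(x)
}
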