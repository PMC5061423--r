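# Correlation mapping between characterizations: normality screening,
# one-parameter Box-Cox transformation, pairwise Spearman correlation with
# the p < 0.001 & |rho| > 0.5 significance rule, and lag estimation.

#' Kolmogorov-Smirnov normality screen
#'
#' Single-sample KS test of a characterization against a normal
#' distribution with the sample's own mean and SD.
#'
#' @param x a `parameter_series` or numeric vector with at least 20
#'   non-missing values.
#' @return list with `statistic` and `p`.
#' @export
ks_normality <- function(x) {
  v <- if (inherits(x, "parameter_series")) x$values else as.numeric(x)
  v <- v[!is.na(v)]
  if (length(v) < 20L) stop("need at least 20 observations for the KS screen")
  s <- stats::sd(v)
  if (s <= .Machine$double.eps) stop("degenerate (constant) input")
  kt <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), s))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' One-parameter Box-Cox transformation
#'
#' `yt = (y^lambda - 1) / lambda` for `lambda != 0`, `yt = log(y)` for
#' `lambda = 0`. With `lambda = "mle"` the value maximizing the Box-Cox
#' profile log-likelihood is selected on a grid over `[-3, 3]`. Inputs must
#' be positive; when `shift = TRUE` a recorded additive shift is applied
#' first if needed.
#'
#' @param x a `parameter_series` or numeric vector.
#' @param lambda numeric exponent or `"mle"`.
#' @param shift allow an automatic positivity shift.
#' @return list with the transformed series (`series`, same class as the
#'   input) and `params` (lambda and the shift used).
#' @export
boxcox_transform <- function(x, lambda = "mle", shift = TRUE) {
  is_ps <- inherits(x, "parameter_series")
  v <- if (is_ps) x$values else as.numeric(x)
  obs <- !is.na(v)
  sh <- 0
  mn <- min(v[obs])
  if (mn <= 0) {
    if (!shift) stop("nonpositive values and no shift allowed")
    sh <- -mn + 1e-6 + 0.01 * abs(mn)
  }
  y <- v[obs] + sh
  if (identical(lambda, "mle")) {
    grid <- seq(-3, 3, by = 0.01)
    n <- length(y)
    sly <- sum(log(y))
    ll <- vapply(grid, function(l) {
      yt <- if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
      -n / 2 * log(stats::var(yt) * (n - 1) / n) + (l - 1) * sly
    }, numeric(1))
    lambda <- grid[which.max(ll)]
  }
  yt <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  out <- v
  out[obs] <- yt
  series <- if (is_ps) { x$values <- out; x } else out
  list(series = series, params = list(lambda = lambda, shift = sh))
}

spearman_p <- function(rho, n, x = NULL, y = NULL, n_perm = 10000L,
                       perm_seed = 1L) {
  if (n > 30L || is.null(x)) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    restore_rng <- local_seed(perm_seed)
    on.exit(restore_rng(), add = TRUE)
    ref <- abs(rho)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      r <- stats::cor(x, sample(y), method = "spearman")
      if (abs(r) >= ref - 1e-12) hits <- hits + 1L
    }
    (hits + 1L) / (n_perm + 1L)
  }
}

#' Pairwise Spearman correlation map
#'
#' Computes the Spearman rho and p-value for every pair of
#' characterizations (on a common grid; optional per-pair lags shift the
#' second series before correlating). An edge is significant when
#' `p < 0.001` and `|rho| > 0.5`. Edges touching the designated reference
#' node are tier "primary" when significant; significant edges between two
#' nodes that are each significantly linked to the reference are
#' "secondary"; all other edges are tier "none".
#'
#' @param series named list of `parameter_series` on a common grid (at
#'   least 2, pairwise overlap of at least 30 samples).
#' @param reference name of the reference node (default `"Lever"`).
#' @param lags optional named numeric vector `"a|b" = lag_s` applied to
#'   pair (a, b): b is advanced by lag_s before correlating.
#' @param p_threshold,rho_threshold significance rule (defaults 0.001, 0.5
#'   on `|rho|`).
#' @return an object of class `correlation_map`: a data frame of edges
#'   (`a`, `b`, `rho`, `p`, `lag_s`, `significant`, `tier`) plus node names
#'   and the reference.
#' @export
spearman_map <- function(series, reference = "Lever", lags = NULL,
                         p_threshold = 0.001, rho_threshold = 0.5) {
  if (length(series) < 2L) stop("need at least 2 series")
  nm <- vapply(series, function(s) s$name, character(1))
  names(series) <- nm
  dt <- stats::median(diff(series[[1L]]$timestamps))
  pairs <- utils::combn(nm, 2L)
  edges <- data.frame(a = pairs[1L, ], b = pairs[2L, ], rho = NA_real_,
                      p = NA_real_, lag_s = 0, significant = FALSE,
                      tier = "none", stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- series[[pairs[1L, i]]]; b <- series[[pairs[2L, i]]]
    lag <- 0
    key1 <- paste0(pairs[1L, i], "|", pairs[2L, i])
    key2 <- paste0(pairs[2L, i], "|", pairs[1L, i])
    if (!is.null(lags)) {
      if (key1 %in% names(lags)) lag <- lags[[key1]]
      else if (key2 %in% names(lags)) lag <- -lags[[key2]]
    }
    va <- a$values; vb <- b$values
    # align on shared timestamps, advancing b by lag
    ta <- round(a$timestamps / dt); tb <- round((b$timestamps - lag) / dt)
    ia <- match(intersect(ta, tb), ta); ib <- match(intersect(ta, tb), tb)
    va <- va[ia]; vb <- vb[ib]
    ok <- !is.na(va) & !is.na(vb)
    if (sum(ok) < 30L)
      stop("pair ", key1, " overlaps on fewer than 30 samples")
    rho <- stats::cor(va[ok], vb[ok], method = "spearman")
    edges$rho[i] <- rho
    edges$lag_s[i] <- lag
    edges$p[i] <- spearman_p(rho, sum(ok), va[ok], vb[ok])
  }
  edges$significant <- edges$p < p_threshold & abs(edges$rho) > rho_threshold
  linked <- unique(c(edges$a[edges$significant & edges$b == reference],
                     edges$b[edges$significant & edges$a == reference]))
  touches_ref <- edges$a == reference | edges$b == reference
  edges$tier[edges$significant & touches_ref] <- "primary"
  sec <- edges$significant & !touches_ref &
    edges$a %in% linked & edges$b %in% linked
  edges$tier[sec] <- "secondary"
  structure(list(nodes = nm, reference = reference, edges = edges),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d nodes, %d significant of %d edges (ref %s)\n",
              length(x$nodes), sum(x$edges$significant), nrow(x$edges),
              x$reference))
  sig <- x$edges[x$edges$significant, c("a", "b", "rho", "p", "tier")]
  if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Estimate the delay between two characterizations
#'
#' Both series are rank-transformed and cross-correlated over a range of
#' time shifts; the returned lag maximizes the correlation. Positive lag
#' means `b` trails `a` by `lag_s` seconds. The estimate is flagged
#' confident when the peak correlation exceeds 0.5.
#'
#' @param a,b `parameter_series` on a common grid.
#' @param max_lag_s maximum |lag| searched, seconds (must be below a
#'   quarter of the common duration).
#' @return list of class `delay_estimate`: `lag_s`, `peak_corr`,
#'   `confident`.
#' @export
estimate_delay <- function(a, b, max_lag_s = 10) {
  dt <- stats::median(diff(a$timestamps))
  n <- min(length(a$values), length(b$values))
  if (max_lag_s >= n * dt / 4)
    stop("max_lag_s must be below a quarter of the common duration")
  ra <- rank(a$values[seq_len(n)], na.last = "keep")
  rb <- rank(b$values[seq_len(n)], na.last = "keep")
  maxk <- as.integer(round(max_lag_s / dt))
  ks <- -maxk:maxk
  cc <- vapply(ks, function(k) {
    if (k >= 0) {
      ia <- seq_len(n - k); ib <- ia + k
    } else {
      ib <- seq_len(n + k); ia <- ib - k
    }
    ok <- !is.na(ra[ia]) & !is.na(rb[ib])
    if (sum(ok) < 10L) return(NA_real_)
    stats::cor(ra[ia][ok], rb[ib][ok])
  }, numeric(1))
  if (all(is.na(cc)))
    return(structure(list(lag_s = 0, peak_corr = NA_real_,
                          confident = FALSE),
                     class = "delay_estimate"))
  best <- which.max(cc)
  structure(list(lag_s = ks[best] * dt, peak_corr = cc[best],
                 confident = isTRUE(cc[best] > 0.5)),
            class = "delay_estimate")
}

#' Serialize or plot a correlation map
#'
#' Always writes the edge list as JSON; optionally draws the map as a
#' circular node layout with line width proportional to `|rho|` (solid for
#' significant edges, dashed otherwise).
#'
#' @param map a [spearman_map()] result.
#' @param out path of the JSON file to write, or `NULL` to skip writing.
#' @param plot draw the map on the current graphics device.
#' @return invisibly, the edge list as a data frame.
#' @export
render_map <- function(map, out = NULL, plot = FALSE) {
  edges <- map$edges
  if (!is.null(out)) {
    jsonlite::write_json(list(nodes = map$nodes, reference = map$reference,
                              edges = edges),
                         out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (plot && length(map$nodes)) {
    k <- length(map$nodes)
    th <- 2 * pi * (seq_len(k) - 1L) / k
    xy <- cbind(cos(th), sin(th))
    graphics::plot(xy, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                   axes = FALSE, xlab = "", ylab = "", pch = 19)
    graphics::text(xy * 1.22, labels = map$nodes, cex = 0.8)
    for (i in seq_len(nrow(edges))) {
      ia <- match(edges$a[i], map$nodes); ib <- match(edges$b[i], map$nodes)
      graphics::segments(xy[ia, 1], xy[ia, 2], xy[ib, 1], xy[ib, 2],
                         lwd = 0.5 + 4 * abs(edges$rho[i]),
                         lty = if (edges$significant[i]) 1 else 2,
                         col = if (edges$significant[i]) "black" else "grey70")
    }
  }
  invisible(edges)
}

#' Read a correlation map back from JSON
#'
#' @param path JSON file written by [render_map()].
#' @return a `correlation_map`.
#' @export
map_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(j$edges)
  structure(list(nodes = j$nodes, reference = j$reference, edges = edges),
            class = "correlation_map")
}
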