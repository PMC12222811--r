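#' Normalize plasmid length by its chromosome
#'
#' Plasmid length divided by the length of the longest chromosome in the
#' same genome, in (0, 1]. The copy-number scaling law is expressed on
#' this scale: its breakpoint near `10^-1.735` corresponds to a plasmid
#' about 1.8% of the chromosome's length.
#'
#' @param length plasmid length(s) in bp.
#' @param chromosome_length longest-chromosome length(s) in bp.
#' @return `length / chromosome_length`.
#' @export
normalize_length <- function(length, chromosome_length) {
  stopifnot(all(chromosome_length > 0))
  length / chromosome_length
}

seg_design <- function(x, bp) cbind(1, x, pmax(x - bp, 0))

seg_rss <- function(x, y, bp) {
  f <- lm.fit(seg_design(x, bp), y)
  sum(f$residuals^2)
}

#' Fit a continuous two-segment (broken-line) regression
#'
#' Least-squares fit of `y = a + b1 * x + b2 * max(0, x - c)`: two line
#' segments meeting continuously at the breakpoint `c`. The breakpoint
#' is profiled over a grid of interior x-quantiles (1%..99%, `n_grid`
#' points, keeping only candidates with at least 3 distinct x values on
#' each side) and then refined by one-dimensional minimization of the
#' residual sum of squares around the best grid cell. Deterministic and
#' derivative-free.
#'
#' Reported: `slope1 = b1`, `slope2 = b1 + b2`, adjusted R-squared (4
#' mean parameters), and Gaussian AIC `n * log(RSS/n) + 2p` with `p = 5`
#' (intercept, two slopes, breakpoint, residual variance). Only AIC
#' differences under this common convention are meaningful.
#'
#' @param x,y numeric predictor and response (typically both log10).
#' @param n_grid number of candidate-breakpoint quantiles (default 513).
#' @return Object of class `segmented_fit`: list with `intercept`,
#'   `slope1`, `slope2`, `breakpoint`, `adj_r2`, `aic`, `rss`, `n`, and
#'   `no_breakpoint_support` (`TRUE` when the profile minimum sits on
#'   the grid boundary or the slope change is negligible, as for data
#'   lying on a single line).
#' @export
fit_segmented <- function(x, y, n_grid = 513) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("degenerate x: fewer than 2 distinct values")
  cand <- unique(quantile(x, seq(0.01, 0.99, length.out = n_grid),
                          names = FALSE, type = 7))
  # a valid breakpoint needs >= 3 distinct x values strictly on each side
  lo <- ux[3]
  hi <- ux[length(ux) - 2]
  cand <- cand[cand > lo & cand < hi]
  if (length(cand) < 2) stop("too few distinct x values for a breakpoint")
  rss <- vapply(cand, function(b) seg_rss(x, y, b), numeric(1))
  i <- which.min(rss)
  interval <- c(cand[max(i - 1L, 1L)], cand[min(i + 1L, length(cand))])
  opt <- optimize(function(b) seg_rss(x, y, b), interval, tol = 1e-8)
  bp <- opt$minimum
  fit <- lm.fit(seg_design(x, bp), y)
  cf <- fit$coefficients
  rss_min <- sum(fit$residuals^2)
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss_min / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 4)
  structure(
    list(
      intercept = unname(cf[1]),
      slope1 = unname(cf[2]),
      slope2 = unname(cf[2] + cf[3]),
      breakpoint = bp,
      adj_r2 = adj_r2,
      aic = n * log(rss_min / n) + 2 * 5,
      rss = rss_min,
      n = n,
      no_breakpoint_support = i %in% c(1L, length(cand)) ||
        abs(cf[3]) < 1e-8
    ),
    class = "segmented_fit"
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "<segmented_fit> n=%d  slope1=%.4f  slope2=%.4f  breakpoint=%.4f\n",
    x$n, x$slope1, x$slope2, x$breakpoint))
  cat(sprintf("  adj R^2 = %.4f   AIC = %.2f%s\n", x$adj_r2, x$aic,
              if (x$no_breakpoint_support) "   [no breakpoint support]"
              else ""))
  invisible(x)
}

#' Predicted values of a segmented fit
#'
#' @param object a [fit_segmented()] object.
#' @param x predictor values.
#' @param ... unused.
#' @return Fitted response values.
#' @export
predict.segmented_fit <- function(object, x, ...) {
  object$intercept + object$slope1 * x +
    (object$slope2 - object$slope1) * pmax(x - object$breakpoint, 0)
}

#' Compare linear, quadratic and segmented models by AIC
#'
#' All three models are scored with the same Gaussian AIC convention
#' `n * log(RSS/n) + 2p` (`p` = mean parameters + 1 for the residual
#' variance; the breakpoint counts as a parameter), so the differences
#' -- and hence the ranking -- are directly comparable.
#'
#' @inheritParams fit_segmented
#' @return Tibble with columns `model`, `aic`, `adj_r2`, `rss`,
#'   `n_params`, sorted by ascending AIC (best first).
#' @export
compare_models <- function(x, y) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  score <- function(X, p_mean) {
    f <- lm.fit(X, y)
    rss <- sum(f$residuals^2)
    r2 <- 1 - rss / tss
    list(aic = n * log(rss / n) + 2 * (p_mean + 1),
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p_mean),
         rss = rss)
  }
  lin <- score(cbind(1, x), 2)
  quad <- score(cbind(1, x, x^2), 3)
  seg <- fit_segmented(x, y)
  out <- tibble::tibble(
    model = c("linear", "quadratic", "segmented"),
    aic = c(lin$aic, quad$aic, seg$aic),
    adj_r2 = c(lin$adj_r2, quad$adj_r2, seg$adj_r2),
    rss = c(lin$rss, quad$rss, seg$rss),
    n_params = c(3L, 4L, 5L)
  )
  dplyr::arrange(out, .data$aic)
}

#' Two-cluster K-means partition of plasmid sizes
#'
#' Plasmid size distributions are bimodal; K-means with K = 2 on
#' log10(length) splits them into a small- and a large-plasmid cluster
#' (raw lengths would let the large mode dominate the squared-error
#' objective and hide the small one). 25 random restarts under a fixed
#' seed; in one dimension this reliably reaches the exact optimum.
#'
#' @param records tibble with columns `length` and `pcn`
#'   (see [read_pcn_table()]).
#' @param seed RNG seed for the restarts (default 1).
#' @return Tibble with one row per cluster (`"small"`, `"large"`):
#'   `cluster`, `n`, and mean/sd/min/max of `pcn` and `length`. Cluster
#'   assignments (`"small"`/`"large"` per record) are attached as
#'   attribute `assignment`; a singleton cluster is permitted.
#' @export
kmeans_two <- function(records, seed = 1) {
  stopifnot(all(c("length", "pcn") %in% names(records)))
  lx <- log10(records$length)
  if (length(unique(lx)) < 2) stop("need >= 2 distinct lengths")
  local_seed(seed)
  km <- kmeans(matrix(lx, ncol = 1), centers = 2, nstart = 25)
  small <- which.min(km$centers)
  lab <- ifelse(km$cluster == small, "small", "large")
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(cluster = lab,
                                   pcn = records$pcn,
                                   length = records$length),
                    .data$cluster),
    n = dplyr::n(),
    pcn_mean = mean(.data$pcn), pcn_sd = sd(.data$pcn),
    pcn_min = min(.data$pcn), pcn_max = max(.data$pcn),
    length_mean = mean(.data$length), length_sd = sd(.data$length),
    length_min = min(.data$length), length_max = max(.data$length),
    .groups = "drop"
  )
  summ <- dplyr::arrange(summ, factor(.data$cluster, c("small", "large")))
  attr(summ, "assignment") <- lab
  summ
}

#' Census of within-genome length/copy-number correlations
#'
#' For every genome with at least `threshold` plasmids, the Pearson
#' correlation between plasmid length and copy number is computed;
#' genomes are counted as negatively (r < 0) or positively (r > 0)
#' correlated. Genomes where r is undefined (zero variance in length or
#' copy number) are excluded and reported. Run at thresholds of 2 and 3
#' plasmids by default.
#'
#' @param records tibble with columns `genome_id`, `length`, `pcn`.
#' @param thresholds integer vector of minimum plasmid counts.
#' @return Tibble with one row per threshold: `threshold`, `n_genomes`,
#'   `n_negative`, `n_positive`, `n_zero`, `n_undefined`,
#'   `mean_r_negative`, `mean_r_positive`.
#' @export
intragenomic_correlations <- function(records, thresholds = c(2L, 3L)) {
  stopifnot(all(c("genome_id", "length", "pcn") %in% names(records)))
  per_genome <- dplyr::summarise(
    dplyr::group_by(records, .data$genome_id),
    n_plasmids = dplyr::n(),
    r = if (dplyr::n() < 2 || sd(.data$length) == 0 || sd(.data$pcn) == 0)
      NA_real_ else cor(.data$length, .data$pcn),
    .groups = "drop"
  )
  dplyr::bind_rows(lapply(thresholds, function(t) {
    g <- per_genome[per_genome$n_plasmids >= t, ]
    ok <- !is.na(g$r)
    tibble::tibble(
      threshold = t,
      n_genomes = nrow(g),
      n_negative = sum(g$r[ok] < 0),
      n_positive = sum(g$r[ok] > 0),
      n_zero = sum(g$r[ok] == 0),
      n_undefined = sum(!ok),
      mean_r_negative = mean(g$r[ok][g$r[ok] < 0]),
      mean_r_positive = mean(g$r[ok][g$r[ok] > 0])
    )
  }))
}

#' Scaling of plasmid DNA content with plasmid length
#'
#' Plasmid DNA content -- copy number x length, here normalized by the
#' chromosome length -- measures the plasmid-derived DNA mass per
#' chromosome copy. If copy number scaled exactly as 1/length, content
#' would be flat (slope 0); in general a copy-number slope `b` implies a
#' content slope `1 + b` on the log-log scale. Fits the same segmented
#' model as [fit_segmented()] with response
#' `log10(pcn * length / chromosome_length)` against
#' `log10(length / chromosome_length)`.
#'
#' @param records tibble with columns `length`, `chromosome_length`,
#'   `pcn`.
#' @inheritParams fit_segmented
#' @return A [fit_segmented()] object.
#' @export
dna_content_scaling <- function(records, n_grid = 513) {
  stopifnot(all(c("length", "chromosome_length", "pcn") %in% names(records)))
  x <- log10(normalize_length(records$length, records$chromosome_length))
  y <- log10(records$pcn * records$length / records$chromosome_length)
  fit_segmented(x, y, n_grid = n_grid)
}

#' Read a per-plasmid copy-number table
#'
#' Expected columns: `genome_id`, `replicon_id`, `length_bp`,
#' `chromosome_length_bp`, `pcn` -- the concatenation of
#' [estimate_pcn()] plasmid rows across genomes.
#'
#' @param path tab-separated file.
#' @return Tibble with columns `genome_id`, `replicon_id`, `length`,
#'   `chromosome_length`, `pcn`.
#' @export
read_pcn_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "replicon_id", "length_bp",
            "chromosome_length_bp", "pcn")
  if (!all(need %in% names(df)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  tibble::tibble(
    genome_id = as.character(df$genome_id),
    replicon_id = as.character(df$replicon_id),
    length = as.numeric(df$length_bp),
    chromosome_length = as.numeric(df$chromosome_length_bp),
    pcn = as.numeric(df$pcn)
  )
}

#' Run the full scaling-law analysis on a plasmid table
#'
#' Computes the segmented log-log fit of copy number against
#' (normalized or raw) plasmid length, the AIC comparison against
#' linear and quadratic models, the two-cluster size summary, the
#' intragenomic correlation census, and the DNA-content scaling fit.
#'
#' @param records tibble as from [read_pcn_table()].
#' @param raw_length fit against raw plasmid length instead of
#'   chromosome-normalized length (default `FALSE`).
#' @param seed seed for the K-means restarts.
#' @return List with elements `segmented`, `models`, `clusters`,
#'   `census`, `dna_content`, and the `x`/`y` vectors used for the main
#'   fit.
#' @export
analyze_pcn_table <- function(records, raw_length = FALSE, seed = 1) {
  x <- if (raw_length) log10(records$length)
       else log10(normalize_length(records$length,
                                   records$chromosome_length))
  y <- log10(records$pcn)
  list(
    segmented = fit_segmented(x, y),
    models = compare_models(x, y),
    clusters = kmeans_two(records, seed = seed),
    census = intragenomic_correlations(records),
    dna_content = dna_content_scaling(records),
    x = x, y = y
  )
}

#' Log-log scatter of copy number against normalized length with the
#' fitted segments
#'
#' @param records tibble as from [read_pcn_table()].
#' @param fit optional [fit_segmented()] object (computed when missing).
#' @param raw_length plot against raw length instead of normalized.
#' @return A ggplot object.
#' @export
plot_scaling <- function(records, fit = NULL, raw_length = FALSE) {
  x <- if (raw_length) log10(records$length)
       else log10(normalize_length(records$length,
                                   records$chromosome_length))
  y <- log10(records$pcn)
  if (is.null(fit)) fit <- fit_segmented(x, y)
  xs <- seq(min(x), max(x), length.out = 200)
  line <- tibble::tibble(x = xs, y = predict(fit, xs))
  ggplot2::ggplot(tibble::tibble(x = x, y = y),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = line, colour = "maroon", linewidth = 1) +
    ggplot2::labs(
      x = if (raw_length) "log10 plasmid length (bp)"
          else "log10 normalized plasmid length",
      y = "log10 plasmid copy number"
    ) +
    ggplot2::theme_minimal()
}

#' Simulate data from a two-segment log-log scaling law
#'
#' Ground-truth generator for the segmented-regression machinery:
#' uniform x over `[xmin, xmax]`, response on the broken line defined by
#' `slope1`, `slope2` and `breakpoint`, plus Gaussian noise.
#'
#' @param n number of points.
#' @param slope1,slope2 segment slopes (defaults follow the empirical
#'   copy-number scaling law: -0.88 before, -0.125 after the break).
#' @param breakpoint breakpoint on the x (log10) scale; default -1.735.
#' @param intercept response at x = 0 on the second segment's
#'   extrapolation through the first (default 0).
#' @param sigma Gaussian noise standard deviation (default 0.4).
#' @param xmin,xmax predictor range; the default `[-4, 0]` spans the
#'   log10 normalized lengths of real plasmids, from ~1 kb plasmids on
#'   ~10 Mb chromosomes up to chromosome-sized replicons.
#' @param seed RNG seed.
#' @return Tibble with columns `x`, `y`.
#' @export
simulate_scaling_data <- function(n = 2000, slope1 = -0.88,
                                  slope2 = -0.125, breakpoint = -1.735,
                                  intercept = 0, sigma = 0.4,
                                  xmin = -4, xmax = 0, seed = 1) {
  local_seed(seed)
  x <- runif(n, xmin, xmax)
  y <- intercept + slope1 * x +
    (slope2 - slope1) * pmax(x - breakpoint, 0) +
    stats::rnorm(n, 0, sigma)
  tibble::tibble(x = x, y = y)
}
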