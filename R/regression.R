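#' Sampling-effort points for a delimitation partition
#'
#' One point per species classified MATCH or SPLIT against the partition:
#' x = number of specimens sampled for that species, y = number of clusters
#' the species touches. Singletons cannot be split and merged/complex taxa
#' have no clean cluster count, so those categories are excluded. When a
#' \code{haplotype_map} is supplied, specimen counts refer to the full
#' pre-collapse dataset (kept-record multiplicities summed); otherwise to
#' the analyzed dataset.
#'
#' @param p a \code{barcode_partition}.
#' @param labels label data frame.
#' @param hap_map optional \code{haplotype_map} from
#'   \code{\link{collapse_haplotypes}}.
#' @return data frame: \code{species}, \code{n_samples}, \code{n_groups},
#'   \code{category}.
#' @export
delimitation_points <- function(p, labels, hap_map = NULL) {
  cls <- classify_all_species(p, labels)
  cls <- cls[cls$category %in% c("MATCH", "SPLIT"), , drop = FALSE]
  if (!nrow(cls))
    stop("no species classified MATCH or SPLIT; nothing to regress")
  cov <- names(p$assignment)
  lab <- labels[labels$id %in% cov, , drop = FALSE]
  mult <- stats::setNames(rep(1L, nrow(lab)), lab$id)
  if (!is.null(hap_map)) {
    idx <- match(lab$id, hap_map$kept_id)
    mult[!is.na(idx)] <- hap_map$multiplicity[idx[!is.na(idx)]]
  }
  n_samples <- vapply(cls$species, function(s)
    sum(mult[lab$id[lab$identified & lab$species == s]]), 1L)
  data.frame(species = cls$species, n_samples = as.integer(n_samples),
             n_groups = cls$n_clusters_touched, category = cls$category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ordinary least squares with slope F-test
#'
#' Simple linear regression of y on x with the F statistic of the slope on
#' (1, n-2) degrees of freedom. A constant response is the degenerate
#' zero-slope fit (r-squared 0, F 0); a constant predictor is an error.
#'
#' @param x numeric predictor, or a data frame whose \code{n_samples} /
#'   \code{n_groups} (or first two numeric) columns are used.
#' @param y numeric response (ignored when \code{x} is a data frame).
#' @return an \code{ols_result} list: \code{slope}, \code{intercept},
#'   \code{F}, \code{df}, \code{p}, \code{r_squared}, \code{n},
#'   \code{mean_x}, \code{se_mean_x}.
#' @export
ols_fit <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    if (all(c("n_samples", "n_groups") %in% names(x))) {
      y <- x$n_groups; x <- x$n_samples
    } else {
      num <- which(vapply(x, is.numeric, TRUE))
      y <- x[[num[2L]]]; x <- x[[num[1L]]]
    }
  }
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("constant predictor; regression undefined")
  if (stats::var(y) == 0) {
    res <- list(slope = 0, intercept = mean(y), F = 0, df = c(1L, n - 2L),
                p = 1, r_squared = 0, n = n, mean_x = mean(x),
                se_mean_x = stats::sd(x) / sqrt(n))
    class(res) <- "ols_result"
    return(res)
  }
  fit <- stats::lm(y ~ x)
  r2 <- stats::cor(x, y)^2
  Fstat <- r2 * (n - 2) / (1 - r2)
  res <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              F = Fstat, df = c(1L, n - 2L),
              p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
              r_squared = r2, n = n, mean_x = mean(x),
              se_mean_x = stats::sd(x) / sqrt(n))
  class(res) <- "ols_result"
  res
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, r2 %.3f, F(%d,%d) = %.3f, p = %.3g, n = %d\n",
              x$slope, x$r_squared, x$df[1L], x$df[2L], x$F, x$p, x$n))
  invisible(x)
}

#' Leave-one-out r-squared
#'
#' Refits the regression with each point omitted, exposing single-point
#' leverage (the outlier diagnostic behind "without this species the
#' r-squared was ...").
#'
#' @inheritParams ols_fit
#' @param names optional point names (species); defaults to data-frame
#'   species column or indices.
#' @return data frame: \code{omitted}, \code{r_squared}.
#' @export
leave_one_out_r2 <- function(x, y = NULL, names = NULL) {
  if (is.data.frame(x)) {
    if (is.null(names) && "species" %in% base::names(x)) names <- x$species
    y <- x$n_groups; x <- x$n_samples
  }
  n <- length(x)
  if (n < 4L) stop("need at least 4 points for leave-one-out")
  if (is.null(names)) names <- as.character(seq_len(n))
  r2 <- vapply(seq_len(n), function(i)
    ols_fit(x[-i], y[-i])$r_squared, 1)
  data.frame(omitted = names, r_squared = r2, stringsAsFactors = FALSE)
}

#' Sampling-effort regression table across delimitation methods
#'
#' @param partitions list of \code{barcode_partition}s.
#' @param labels label data frame.
#' @param hap_map optional \code{haplotype_map} (specimen counts then refer
#'   to the full pre-collapse dataset).
#' @return data frame, one row per method: \code{method}, \code{df},
#'   \code{F}, \code{p}, \code{r_squared}, \code{mean_samples},
#'   \code{se_mean_samples}, \code{n_points}.
#' @export
regression_summary <- function(partitions, labels, hap_map = NULL) {
  meth <- if (!is.null(names(partitions)) && all(nzchar(names(partitions))))
    names(partitions) else vapply(partitions, `[[`, "", "method")
  rows <- lapply(seq_along(partitions), function(i) {
    pts <- tryCatch(delimitation_points(partitions[[i]], labels, hap_map),
                    error = function(e) NULL)
    if (is.null(pts) || nrow(pts) < 3L || stats::var(pts$n_samples) == 0)
      return(data.frame(method = meth[i], df = NA_character_, F = NA_real_,
                        p = NA_real_, r_squared = NA_real_,
                        mean_samples = NA_real_, se_mean_samples = NA_real_,
                        n_points = if (is.null(pts)) 0L else nrow(pts),
                        stringsAsFactors = FALSE))
    fit <- ols_fit(pts)
    data.frame(method = meth[i],
               df = paste(fit$df, collapse = ","),
               F = fit$F, p = fit$p, r_squared = fit$r_squared,
               mean_samples = fit$mean_x, se_mean_samples = fit$se_mean_x,
               n_points = fit$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
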