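#' Min-max scale feature columns to [0, 1]
#'
#' NMF requires a nonnegative input; each feature column is mapped to
#' [0, 1] by its own range. Constant columns map to 0.
#'
#' @param X numeric matrix (patients x features).
#' @return matrix of the same shape.
#' @export
minmax_scale <- function(X) {
  X <- as.matrix(X)
  apply(X, 2, function(x) {
    r <- range(x, finite = TRUE)
    if (r[2] == r[1]) rep(0, length(x)) else (x - r[1]) / (r[2] - r[1])
  })
}

#' Non-negative matrix factorization (multiplicative updates)
#'
#' Factorizes a nonnegative patients-by-features matrix as X ~ W H with
#' W (n x rank) and H (rank x p) entrywise nonnegative, minimizing the
#' Frobenius loss by Lee-Seung multiplicative updates (monotone
#' non-increasing loss). Random uniform initialization from `seed`.
#'
#' @param X nonnegative matrix; scale features with [minmax_scale()]
#'   first.
#' @param rank factorization rank (< min(dim(X))).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol iteration cap and relative-loss convergence
#'   tolerance.
#' @return An object of class `nmf_result`: `W`, `H`,
#'   `reconstruction_error` (Frobenius norm), `loss_trace`, `rank`,
#'   `restart_seed`, `converged`.
#' @export
nmf_fit <- function(X, rank, seed = 1L, max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  if (any(X < 0))
    stop("nmf_fit: X has negative entries; rescale (e.g. minmax_scale) first")
  n <- nrow(X); p <- ncol(X)
  if (rank >= min(n, p)) stop("nmf_fit: rank must be < min(dim(X))")
  set.seed(seed)
  W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(stats::runif(rank * p, 0.1, 1), rank, p)
  eps <- .Machine$double.eps
  loss <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    l <- sum((X - W %*% H)^2)
    loss <- c(loss, l)
    if (is.finite(prev) && (prev - l) <= tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- l
  }
  structure(list(W = W, H = H, reconstruction_error = sqrt(loss[length(loss)]),
                 loss_trace = loss, rank = rank, restart_seed = seed,
                 converged = converged),
            class = "nmf_result")
}

# hard labels from an NMF fit: dominant basis component per patient
nmf_labels <- function(fit) max.col(fit$W, ties.method = "first")

#' NMF consensus rank survey
#'
#' For each candidate rank, runs `n_restarts` randomly initialized NMF
#' fits, records patient co-assignment (by dominant basis component)
#' into a consensus matrix, and scores the rank by the cophenetic
#' correlation of average-linkage clustering of 1 - consensus. A restart
#' that leaves a component empty is resampled with a fresh seed (counted
#' in `degenerate_restarts`). The chosen rank maximizes the cophenetic
#' correlation; the full survey is returned so the choice can be
#' overridden by eye, as consensus maps usually are.
#'
#' @param X nonnegative matrix (patients x features), e.g. from
#'   [minmax_scale()].
#' @param ranks candidate ranks (default 2:6).
#' @param n_restarts random restarts per rank (default 20).
#' @param seed master seed; restart seeds derive from it.
#' @param max_iter per-fit iteration cap.
#' @return list of class `consensus_survey`: `summaries` (per rank, a
#'   `consensus_summary` with `consensus_matrix`, `cophenetic`, `rank`,
#'   `degenerate_restarts`), `chosen_rank`, `survey` (data.frame
#'   rank/cophenetic).
#' @export
rank_survey <- function(X, ranks = 2:6, n_restarts = 20L, seed = 1L,
                        max_iter = 300L) {
  X <- as.matrix(X)
  n <- nrow(X)
  summaries <- list()
  for (r in ranks) {
    C <- matrix(0, n, n)
    degen <- 0L
    done <- 0L
    s <- seed * 1000L + r * 100L
    while (done < n_restarts) {
      s <- s + 1L
      fit <- nmf_fit(X, r, seed = s, max_iter = max_iter)
      lab <- nmf_labels(fit)
      if (length(unique(lab)) < r) { degen <- degen + 1L
        if (degen > 50L * n_restarts)
          stop("rank_survey: rank ", r, " cannot populate all components")
        next
      }
      C <- C + outer(lab, lab, "==")
      done <- done + 1L
    }
    C <- C / n_restarts
    diag(C) <- 1
    dmat <- stats::as.dist(1 - C)
    coph <- if (stats::sd(dmat) == 0) 1 else
      stats::cor(dmat, stats::cophenetic(stats::hclust(dmat, "average")))
    summaries[[as.character(r)]] <-
      structure(list(consensus_matrix = C, cophenetic = coph, rank = r,
                     degenerate_restarts = degen),
                class = "consensus_summary")
  }
  survey <- data.frame(rank = ranks,
                       cophenetic = vapply(summaries, `[[`, 0, "cophenetic"))
  chosen <- ranks[which.max(survey$cophenetic)]
  structure(list(summaries = summaries, chosen_rank = chosen,
                 survey = survey),
            class = "consensus_survey")
}

#' Cluster assignment from a consensus matrix
#'
#' Average-linkage hierarchical clustering of 1 - consensus, cut at the
#' summary's rank. Deterministic given the consensus matrix.
#'
#' @param summary a `consensus_summary` (one element of
#'   [rank_survey()]`$summaries`) or a `consensus_survey` (its chosen
#'   rank is used).
#' @return integer cluster labels, one per patient.
#' @export
assign_clusters <- function(summary) {
  if (inherits(summary, "consensus_survey"))
    summary <- summary$summaries[[as.character(summary$chosen_rank)]]
  stopifnot(inherits(summary, "consensus_summary"))
  hc <- stats::hclust(stats::as.dist(1 - summary$consensus_matrix), "average")
  stats::cutree(hc, k = summary$rank)
}

#' Chi-square tests of cluster labels against clinical covariates
#'
#' One test per discrete covariate on the labels-by-category contingency
#' table (no continuity correction). Categories with zero margin are
#' dropped with a warning.
#'
#' @param labels cluster labels.
#' @param clinical data.frame of discrete covariates.
#' @return data.frame: covariate, statistic, df, p_value.
#' @export
cluster_vs_clinical <- function(labels, clinical) {
  stopifnot(nrow(clinical) == length(labels))
  res <- lapply(names(clinical), function(v) {
    x <- factor(clinical[[v]])
    tab <- table(labels, x)
    empty <- colSums(tab) == 0
    if (any(empty)) {
      warning("cluster_vs_clinical: dropping empty categories of ", v, ": ",
              paste(colnames(tab)[empty], collapse = ", "))
      tab <- tab[, !empty, drop = FALSE]
    }
    if (ncol(tab) < 2L || nrow(tab) < 2L)
      return(data.frame(covariate = v, statistic = NA, df = NA,
                        p_value = NA))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(covariate = v, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_value = ct$p.value)
  })
  do.call(rbind, res)
}

#' Kaplan-Meier curves and log-rank test between clusters
#'
#' @param labels cluster labels.
#' @param cohort a `survival_cohort` data.frame.
#' @param endpoint one of `"os"`, `"dfs"`, `"lc"`, `"dc"`.
#' @return list: `fit` (a [survival::survfit] per cluster), `statistic`,
#'   `p_value`, `flag` (set when some cluster has no events).
#' @export
km_logrank <- function(labels, cohort, endpoint = "os") {
  tcol <- paste0("time_", endpoint); ecol <- paste0("event_", endpoint)
  if (!all(c(tcol, ecol) %in% names(cohort)))
    stop("km_logrank: endpoint ", endpoint, " not present in cohort")
  df <- data.frame(time = cohort[[tcol]], event = cohort[[ecol]],
                   group = factor(labels))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, df)
  flag <- NULL
  ev_by_grp <- tapply(df$event, df$group, sum)
  if (any(ev_by_grp == 0))
    flag <- "some cluster has no events; log-rank unreliable"
  if (stats::var(as.integer(df$group)) == 0 || sum(df$event) == 0) {
    stat <- 0; p <- 1
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, df)
    stat <- sd_$chisq
    p <- stats::pchisq(stat, length(sd_$n) - 1, lower.tail = FALSE)
  }
  list(fit = fit, statistic = stat, p_value = p, flag = flag)
}

#' Plot Kaplan-Meier curves per cluster
#' @param km result of [km_logrank()]; @param path output PNG;
#' @param main title.
#' @export
km_plot <- function(km, path, main = "Overall survival by cluster") {
  grDevices::png(path, width = 560, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot(km$fit, col = seq_along(km$fit$strata), lwd = 2,
                 xlab = "Time (months)", ylab = "Survival probability",
                 main = main)
  graphics::legend("topright", legend = names(km$fit$strata),
                   col = seq_along(km$fit$strata), lwd = 2, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", km$p_value), side = 3,
                  line = -1.5, adj = 0.05)
  invisible(path)
}

#' Plot a consensus matrix heatmap
#' @param summary a `consensus_summary`; @param path output PNG.
#' @export
consensus_plot <- function(summary, path) {
  if (inherits(summary, "consensus_survey"))
    summary <- summary$summaries[[as.character(summary$chosen_rank)]]
  C <- summary$consensus_matrix
  ord <- stats::hclust(stats::as.dist(1 - C), "average")$order
  grDevices::png(path, width = 520, height = 520)
  on.exit(grDevices::dev.off())
  graphics::image(C[ord, ord], col = grDevices::hcl.colors(64, "Blues 3",
                                                           rev = TRUE),
                  axes = FALSE,
                  main = sprintf("Consensus map, rank %d (cophenetic %.3f)",
                                 summary$rank, summary$cophenetic))
  invisible(path)
}
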