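#' Assign samples to peaks of a fitted model
#'
#' Each sample goes to the mixture component maximizing its posterior
#' probability (ties to the lower-indexed peak); peaks are indexed 1..K by
#' ascending component mean. Zeros under zero-inflated models and censored
#' values under left-truncated models get label 0 ("insignificant
#' expression"); for ZIP/ZINB, zeros are labelled 0 when the inflation
#' posterior exceeds the base-law posterior. Unimodal fits label every
#' (non-zero, non-censored) sample 1.
#'
#' @param x Data vector on the fit's scale.
#' @param fit A converged `m3s_fit`.
#' @return Integer vector of labels in `0..K`.
#' @export
assign_peaks <- function(x, fit) {
  stopifnot(inherits(fit, "m3s_fit"))
  if (!isTRUE(fit$converged))
    stop_m3s("not_converged", "assign_peaks requires a converged fit")
  p <- fit$params
  n <- length(x)
  labels <- rep(1L, n)
  switch(fit$model,
    MG = {
      labels <- mix_map_component(x, p)
    },
    ZIMG = {
      labels <- mix_map_component(x, p)
      labels[x == 0] <- 0L
    },
    LTMG = {
      labels <- mix_map_component(x, p)
      labels[x <= p$zcut] <- 0L
    },
    ZIG = { labels[x == 0] <- 0L },
    LTG = { labels[x <= p$zcut] <- 0L },
    ZIP = {
      post0 <- p$pi0 / (p$pi0 + (1 - p$pi0) * stats::dpois(0, p$lambda))
      labels[x == 0 & post0 >= 0.5] <- 0L
    },
    ZINB = {
      post0 <- p$pi0 /
        (p$pi0 + (1 - p$pi0) * stats::dnbinom(0, size = p$size, prob = p$prob))
      labels[x == 0 & post0 >= 0.5] <- 0L
    },
    { labels <- rep(1L, n) }
  )
  labels
}

# MAP component of a Gaussian mixture, components ordered by mean,
# posterior ties resolved toward the lower-indexed peak.
mix_map_component <- function(x, p) {
  ord <- order(p$mus)
  w <- p$weights[ord]; mu <- p$mus[ord]; s <- p$sigmas[ord]
  lp <- vapply(seq_along(w), function(k) {
    log(w[k]) + stats::dnorm(x, mu[k], s[k], log = TRUE)
  }, numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  as.integer(apply(lp, 1, which.max))
}

#' Upper-tail hypergeometric enrichment probability
#'
#' P(X >= overlap) for X ~ Hypergeometric(population, class_size,
#' peak_size): the chance that a random peak of the observed size overlaps
#' the class at least as much as observed.
#'
#' @param overlap Observed overlap between peak members and class members.
#' @param peak_size Number of samples in the peak.
#' @param class_size Number of samples in the class.
#' @param population Total number of samples.
#' @return One-sided p-value in (0, 1].
#' @export
hypergeom_enrichment <- function(overlap, peak_size, class_size, population) {
  if (overlap > min(peak_size, class_size) || peak_size > population ||
      class_size > population || overlap < 0)
    stop_m3s("invalid_data", "inconsistent hypergeometric counts")
  if (overlap == 0) return(1)
  stats::phyper(overlap - 1, m = class_size, n = population - class_size,
                k = peak_size, lower.tail = FALSE)
}

#' Peak-membership differential expression test
#'
#' For every gene with at least one non-zero peak and every (peak, class)
#' pair, tests whether the samples assigned to the peak are enriched in the
#' class by an upper-tail hypergeometric test; BH-FDR is computed across
#' all tested (gene, peak, class) triples. A gene is flagged differentially
#' expressed when any of its non-zero peaks has FDR below the threshold.
#'
#' @param matrix The gene x sample matrix `selection` was computed on.
#' @param classes Per-sample class labels (character/factor, length =
#'   number of samples) or a named vector matched against column names.
#' @param selection An `m3s_result` from [m3s()].
#' @param fdr_threshold DE flagging threshold (default 0.05).
#' @param top_peak_only Test only each gene's highest peak.
#' @return data.frame of class `m3s_detest`: gene, peak, class_name,
#'   overlap, peak_size, class_size, population, p_value, fdr, de.
#' @export
m3s_test <- function(matrix, classes, selection, fdr_threshold = 0.05,
                     top_peak_only = FALSE) {
  m <- as.matrix(matrix)
  stopifnot(inherits(selection, "m3s_result"))
  if (!is.null(names(classes)) && !is.null(colnames(m))) {
    if (!all(colnames(m) %in% names(classes)))
      stop_m3s("label_mismatch", "classes missing for some samples")
    classes <- classes[colnames(m)]
  }
  if (length(classes) != ncol(m))
    stop_m3s("label_mismatch", "classes must cover all ", ncol(m),
             " samples (got ", length(classes), ")")
  classes <- as.character(classes)
  tm <- apply_normalization(m, selection$normalization)
  population <- ncol(m)
  class_levels <- unique(classes)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    g <- selection$summary$gene[i]
    best <- selection$summary$best_model[i]
    fit <- selection$fits[[i]][[best]]
    x <- if (is_count_model(best)) m[i, ] else tm[i, ]
    labels <- assign_peaks(x, fit)
    peaks <- sort(unique(labels[labels > 0L]))
    if (length(peaks) == 0L) next
    if (top_peak_only) peaks <- max(peaks)
    for (pk in peaks) {
      in_peak <- labels == pk
      for (cl in class_levels) {
        in_class <- classes == cl
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, peak = pk, class_name = cl,
          overlap = sum(in_peak & in_class),
          peak_size = sum(in_peak), class_size = sum(in_class),
          population = population, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), peak = integer(0),
               class_name = character(0), overlap = integer(0),
               peak_size = integer(0), class_size = integer(0),
               population = integer(0), stringsAsFactors = FALSE)
  out$p_value <- mapply(hypergeom_enrichment, out$overlap, out$peak_size,
                        out$class_size, out$population)
  out$p_value <- as.numeric(out$p_value)
  out$fdr <- fdr_adjust(out$p_value)
  out$de <- !is.na(out$fdr) & out$fdr < fdr_threshold
  class(out) <- c("m3s_detest", "data.frame")
  out
}
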