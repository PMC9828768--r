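#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes. Duplicated
#' members within a set are dropped.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1], call. = FALSE)
    unique(f[-(1:2)])
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(!is.null(names(gene_sets)))
  writeLines(vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), character(1)), path)
}

#' Read a ranked gene list (RNK)
#'
#' Two tab-separated columns (gene, score), no header; the result is sorted
#' by descending score.
#'
#' @param path RNK file path.
#' @return data.frame with `gene` and `score`, sorted descending.
#' @export
read_rnk <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene", "score"),
                         colClasses = c("character", "numeric"))
  ranked_list(d$gene, d$score)
}

#' Write a ranked gene list (RNK)
#'
#' @param ranking data.frame with `gene` and `score`.
#' @param path output path.
#' @export
write_rnk <- function(ranking, path) {
  utils::write.table(ranking[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Construct a validated ranked gene list
#'
#' @param gene character vector of unique gene names.
#' @param score finite numeric scores (conventionally -log10 p).
#' @return data.frame sorted by descending score, class `ranked_list`.
#' @export
ranked_list <- function(gene, score) {
  if (anyDuplicated(gene)) stop("gene names must be unique", call. = FALSE)
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  o <- order(score, decreasing = TRUE)
  structure(data.frame(gene = as.character(gene)[o], score = score[o]),
            class = c("ranked_list", "data.frame"))
}

#' Simulate a ranked gene list with planted enrichment
#'
#' Every gene in the universe receives a uniform p-value converted to a
#' -log10 p score; genes belonging to the planted sets get `planted_effect`
#' added to their score, pushing them toward the top of the ranking. The
#' universe is the union of all gene-set members, padded with filler genes up
#' to `n_genes`.
#'
#' @param gene_sets named list of gene sets (GMT-style).
#' @param planted_set_names names of the sets to plant (must exist).
#' @param planted_effect non-negative shift added to planted genes' scores.
#' @param n_genes universe size.
#' @param seed integer seed.
#' @return a [ranked_list()].
#' @export
simulate_ranked_list <- function(gene_sets, planted_set_names = character(),
                                 planted_effect = 0, n_genes = 2000,
                                 seed = 1) {
  stopifnot(planted_effect >= 0)
  missing_sets <- setdiff(planted_set_names, names(gene_sets))
  if (length(missing_sets))
    stop("planted set(s) not found: ", paste(missing_sets, collapse = ", "),
         call. = FALSE)
  members <- unique(unlist(gene_sets, use.names = FALSE))
  if (length(members) > n_genes)
    stop("n_genes smaller than the gene-set universe", call. = FALSE)
  filler <- sprintf("GENE%05d", seq_len(n_genes - length(members)))
  genes <- c(members, filler)
  planted <- unique(unlist(gene_sets[planted_set_names], use.names = FALSE))
  with_seed(derive_seed(seed, "ranked_list"), {
    score <- -log10(runif(length(genes)))
    score[genes %in% planted] <- score[genes %in% planted] + planted_effect
    ranked_list(genes, score)
  })
}

# Core weighted Kolmogorov-Smirnov enrichment statistic.
# w_all: |score|^alpha over the whole (ordered) ranking; pos: sorted hit
# positions. Returns ES, index of the extremum hit, and its sign.
es_core <- function(w_all, pos, n_universe) {
  k <- length(pos)
  w <- w_all[pos]
  tw <- sum(w)
  if (tw == 0) w <- rep(1, k); tw <- sum(w)
  cum_hit <- cumsum(w) / tw
  miss_before <- (pos - seq_len(k)) / (n_universe - k)
  top <- cum_hit - miss_before            # running sum just after each hit
  bottom <- c(0, cum_hit[-k]) - miss_before  # just before each hit
  imax <- which.max(top)
  imin <- which.min(bottom)
  if (top[imax] >= -bottom[imin]) list(es = top[imax], idx = imax, sign = 1L)
  else list(es = bottom[imin], idx = imin, sign = -1L)
}

#' Preranked enrichment score with a gene-permutation null
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: walking down the
#' ranking, the sum increments at set members ("hits") proportionally to
#' `|score|^weight_exponent` and decrements evenly at misses; the enrichment
#' score (ES) is the maximum deviation from zero. The permutation p-value
#' compares the observed ES against `nperm` random gene-label permutations
#' (random hit positions of the same size), one-sided on the observed sign.
#' The leading edge contains the hit genes at or before the ES extremum
#' (at or after it for negative ES).
#'
#' @param ranking a [ranked_list()].
#' @param gset character vector of member genes (or one element of a
#'   [read_gmt()] list).
#' @param weight_exponent hit-weight exponent (0 = classic KS, 1 = weighted).
#' @param nperm number of gene permutations for the null (>= 1).
#' @param seed optional seed for the permutation stream.
#' @return an object of class `enrichment_result`: `es`, `nes`, `perm_p`,
#'   `leading_edge`, `n_hits`.
#' @export
enrichment_score <- function(ranking, gset, weight_exponent = 1, nperm = 1000,
                             seed = NULL) {
  stopifnot(inherits(ranking, "data.frame"), nperm >= 1)
  pos <- sort(match(gset, ranking$gene))
  pos <- pos[!is.na(pos)]
  n <- nrow(ranking)
  if (!length(pos))
    stop(structure(class = c("nfemg_no_overlap", "error", "condition"),
                   list(message = "gene set has no overlap with the ranking",
                        call = sys.call())))
  if (length(pos) >= n)
    stop("gene set must be smaller than the universe", call. = FALSE)
  w_all <- abs(ranking$score)^weight_exponent
  obs <- es_core(w_all, pos, n)
  k <- length(pos)
  draw_null <- function() {
    es_core(w_all, sort(sample.int(n, k)), n)$es
  }
  null_es <- if (is.null(seed)) replicate(nperm, draw_null())
             else with_seed(seed, replicate(nperm, draw_null()))
  # one-sided p against the same-sign half of the null, the standard GSEA
  # convention; exactly calibrated for an exchangeable null set
  same_sign <- null_es[sign(null_es) == obs$sign]
  perm_p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
  le <- if (obs$sign > 0) pos[seq_len(obs$idx)] else pos[obs$idx:k]
  structure(list(es = obs$es, nes = nes, perm_p = perm_p,
                 leading_edge = ranking$gene[le], n_hits = k),
            class = "enrichment_result")
}

#' Monte-Carlo ensemble of preranked enrichment analyses
#'
#' Enrichment estimates with a permutation null are themselves stochastic;
#' to stabilise the selection of significant pathways, the analysis is
#' embedded in a Monte-Carlo ensemble: [enrichment_score()] is run
#' `n_iterations` times (default 1000) with independent permutation streams,
#' and each set's selection frequency is the fraction of iterations in which
#' its permutation p-value fell below `alpha`. Per-gene leading-edge
#' frequencies (fraction of iterations in which a gene sat in the leading
#' edge of its set while the set was selected) are recorded for the
#' consensus rule of [leading_edge_consensus()]. Optionally,
#' `resample_ranking` regenerates the ranking each iteration (e.g. a
#' parametric resample of the upstream scores), making iterations fully
#' independent; the default varies only the permutation streams.
#'
#' @param ranking a [ranked_list()].
#' @param gene_sets named list of gene sets.
#' @param n_iterations ensemble size (default 1000).
#' @param nperm permutations per iteration.
#' @param alpha per-iteration significance level on the permutation p.
#' @param weight_exponent passed to [enrichment_score()].
#' @param seed integer seed; fully determines the ensemble.
#' @param resample_ranking optional `function(iteration, seed)` returning a
#'   fresh [ranked_list()] for that iteration.
#' @return an object of class `consensus_result`: `set_frequency` (named,
#'   in `[0, 1]`), `significant_sets` (frequency above `consensus_threshold`),
#'   `leading_edge_frequency` (named list per set), `n_iterations`, `alpha`.
#' @param consensus_threshold selection frequency above which a set is
#'   reported as a consensus significant pathway.
#' @export
mc_ensemble <- function(ranking, gene_sets, n_iterations = 1000, nperm = 1000,
                        alpha = 0.05, weight_exponent = 1, seed = 1,
                        consensus_threshold = 0.8, resample_ranking = NULL) {
  stopifnot(n_iterations >= 1, !is.null(names(gene_sets)))
  sets <- names(gene_sets)
  sel_count <- stats::setNames(numeric(length(sets)), sets)
  le_hits <- stats::setNames(vector("list", length(sets)), sets)
  for (t in seq_len(n_iterations)) {
    rk <- if (is.null(resample_ranking)) ranking
          else resample_ranking(t, derive_seed(seed, "resample", t))
    for (s in sets) {
      res <- tryCatch(
        enrichment_score(rk, gene_sets[[s]], weight_exponent, nperm,
                         seed = derive_seed(seed, "perm", t, s)),
        nfemg_no_overlap = function(e) NULL)
      if (is.null(res)) next
      if (res$perm_p < alpha) {
        sel_count[s] <- sel_count[s] + 1
        le_hits[[s]][[length(le_hits[[s]]) + 1L]] <- res$leading_edge
      }
    }
  }
  le_freq <- lapply(le_hits, function(x) {
    if (!length(x)) return(numeric(0))
    tab <- table(unlist(x, use.names = FALSE)) / n_iterations
    sort(stats::setNames(as.numeric(tab), names(tab)), decreasing = TRUE)
  })
  freq <- sel_count / n_iterations
  structure(list(set_frequency = freq,
                 significant_sets = names(freq)[freq > consensus_threshold],
                 leading_edge_frequency = le_freq,
                 n_iterations = n_iterations, alpha = alpha,
                 consensus_threshold = consensus_threshold),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d iterations, alpha %.3g\n",
              x$n_iterations, x$alpha))
  print(round(x$set_frequency, 3))
  invisible(x)
}

#' Consensus leading-edge genes
#'
#' Genes whose leading-edge frequency over the ensemble exceeds
#' `freq_threshold` strictly (a gene selected in exactly 80 percent of the
#' iterations is excluded at the default threshold), sorted by frequency then
#' name.
#'
#' @param result a [mc_ensemble()] result.
#' @param set gene-set name; when `NULL`, frequencies are pooled by maximum
#'   over sets.
#' @param freq_threshold strict frequency threshold (default 0.8).
#' @return data.frame with `gene` and `frequency`.
#' @export
leading_edge_consensus <- function(result, set = NULL, freq_threshold = 0.8) {
  stopifnot(inherits(result, "consensus_result"))
  freq <- if (!is.null(set)) {
    if (!set %in% names(result$leading_edge_frequency))
      stop("unknown set: ", set, call. = FALSE)
    result$leading_edge_frequency[[set]]
  } else {
    all <- unlist(unname(result$leading_edge_frequency))
    if (length(all)) tapply(all, names(all), max) else numeric(0)
  }
  freq <- freq[freq > freq_threshold]
  o <- order(-freq, names(freq))
  data.frame(gene = names(freq)[o], frequency = unname(freq)[o],
             row.names = NULL)
}
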