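#' Simulate a log2 protein-abundance matrix with site and age effects
#'
#' Emulates a two-site (mandibular vs subiliac), two-age (young vs old)
#' whole-LN bulk proteome: per-protein baseline log2 abundances are
#' Normal(mu_i, sigma_i) with mu_i drawn from the empirical dynamic range
#' of label-free proteomics (roughly 18 +/- 3 on the log2 scale) and
#' sigma_i from 0.2-0.6. Designated proteins receive additive effects:
#' `n_site` proteins a site effect (mandibular minus subiliac) of size
#' `site_effect`, `n_age_both` proteins an age effect (old minus young) of
#' size `age_effect` in both sites, `n_age_site` an age effect in one site
#' only.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group samples per site x age group (>= 2).
#' @param effects list with `n_site`, `site_effect`, `n_age_both`,
#'   `age_effect`, `n_age_site` (defaults 0 each).
#' @param seed integer seed.
#' @return list with `mat` (an `abundance_matrix`: numeric matrix proteins
#'   x samples), `design` (data.frame sample_id, site, age, mouse_id) and
#'   `truth` (data.frame protein_id, site_de, age_de_both, age_de_mand).
#' @export
simulate_abundances <- function(n_proteins = 1000L, n_per_group = 10L,
                                effects = list(), seed = 1L) {
  stopifnot(n_proteins >= 1L, n_per_group >= 2L)
  ef <- modifyList(list(n_site = 0L, site_effect = 1.79,
                        n_age_both = 0L, age_effect = 1,
                        n_age_site = 0L), effects)
  stopifnot(ef$n_site + ef$n_age_both + ef$n_age_site <= n_proteins)
  with_seed(seed, {
    sites <- rep(c("mandibular", "subiliac"), each = 2L * n_per_group)
    ages <- rep(rep(c("young", "old"), each = n_per_group), 2L)
    n <- length(sites)
    design <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      site = sites, age = ages,
      mouse_id = sprintf("M%02d", rep(seq_len(n / 2), 2L)))
    ids <- sprintf("P%04d", seq_len(n_proteins))
    mu <- rnorm(n_proteins, 18, 3)
    sigma <- runif(n_proteins, 0.2, 0.6)
    mat <- matrix(rnorm(n_proteins * n, rep(mu, n), rep(sigma, n)),
                  n_proteins, n, dimnames = list(ids, design$sample_id))
    site_de <- seq_len(ef$n_site)
    age_both <- ef$n_site + seq_len(ef$n_age_both)
    age_mand <- ef$n_site + ef$n_age_both + seq_len(ef$n_age_site)
    is_mand <- design$site == "mandibular"
    is_old <- design$age == "old"
    if (ef$n_site > 0)
      mat[site_de, is_mand] <- mat[site_de, is_mand] + ef$site_effect
    if (ef$n_age_both > 0)
      mat[age_both, is_old] <- mat[age_both, is_old] + ef$age_effect
    if (ef$n_age_site > 0)
      mat[age_mand, is_old & is_mand] <-
        mat[age_mand, is_old & is_mand] + ef$age_effect
    truth <- data.frame(protein_id = ids,
                        site_de = seq_len(n_proteins) %in% site_de,
                        age_de_both = seq_len(n_proteins) %in% age_both,
                        age_de_mand = seq_len(n_proteins) %in%
                          c(age_both, age_mand))
    class(mat) <- c("abundance_matrix", class(mat))
    list(mat = mat, design = design, truth = truth)
  })
}

contrast_groups <- function(design, contrast) {
  ok <- c("mand_vs_sub_mean", "mand_vs_sub_young", "mand_vs_sub_old",
          "sub_vs_mand_mean", "sub_vs_mand_young", "sub_vs_mand_old",
          "old_vs_young_sub", "old_vs_young_mand")
  if (!contrast %in% ok)
    stop("unknown contrast '", contrast, "'; one of: ",
         paste(ok, collapse = ", "))
  sel_site <- function(s) design$site == s
  sel_age <- function(a) design$age == a
  switch(contrast,
    mand_vs_sub_mean = list(a = sel_site("mandibular"),
                            b = sel_site("subiliac"), by_age = TRUE),
    mand_vs_sub_young = list(a = sel_site("mandibular") & sel_age("young"),
                             b = sel_site("subiliac") & sel_age("young"),
                             by_age = FALSE),
    mand_vs_sub_old = list(a = sel_site("mandibular") & sel_age("old"),
                           b = sel_site("subiliac") & sel_age("old"),
                           by_age = FALSE),
    sub_vs_mand_mean = list(a = sel_site("subiliac"),
                            b = sel_site("mandibular"), by_age = TRUE),
    sub_vs_mand_young = list(a = sel_site("subiliac") & sel_age("young"),
                             b = sel_site("mandibular") & sel_age("young"),
                             by_age = FALSE),
    sub_vs_mand_old = list(a = sel_site("subiliac") & sel_age("old"),
                           b = sel_site("mandibular") & sel_age("old"),
                           by_age = FALSE),
    old_vs_young_sub = list(a = sel_age("old") & sel_site("subiliac"),
                            b = sel_age("young") & sel_site("subiliac"),
                            by_age = FALSE),
    old_vs_young_mand = list(a = sel_age("old") & sel_site("mandibular"),
                             b = sel_age("young") & sel_site("mandibular"),
                             by_age = FALSE))
}

#' Group-mean log2 fold changes
#'
#' Difference of group means of log2 abundances. For the pooled "mean"
#' site contrasts, each site's value is the mean of its two age-group
#' means (balanced with respect to age), then differenced.
#'
#' @param mat proteins x samples matrix of log2 abundances.
#' @param design design data.frame (`sample_id`, `site`, `age`).
#' @param contrast one of `mand_vs_sub_{mean,young,old}`,
#'   `sub_vs_mand_{mean,young,old}`, `old_vs_young_{sub,mand}`.
#' @return named numeric vector of per-protein log2 fold changes.
#' @export
group_log2fc <- function(mat, design, contrast = "mand_vs_sub_mean") {
  g <- contrast_groups(design, contrast)
  grp_mean <- function(sel) {
    if (g$by_age) {
      (rowMeans(mat[, sel & design$age == "young", drop = FALSE]) +
       rowMeans(mat[, sel & design$age == "old", drop = FALSE])) / 2
    } else {
      rowMeans(mat[, sel, drop = FALSE])
    }
  }
  grp_mean(g$a) - grp_mean(g$b)
}

#' Normality-gated per-protein differential test
#'
#' For each protein, both contrast groups are tested for normality with
#' the Shapiro-Wilk test; if all groups pass (p > `alpha_norm`) a
#' two-sided Welch t-test is applied, otherwise a two-sided Wilcoxon
#' rank-sum test. Groups with zero variance cannot be normality-tested and
#' route to the Wilcoxon branch. Proteins quantified (non-missing) in less
#' than `min_quantified` of the samples of either group are dropped before
#' testing.
#'
#' @param mat proteins x samples log2 abundance matrix (may contain NA).
#' @param design design data.frame.
#' @param contrast contrast name (see [group_log2fc()]).
#' @param alpha_norm Shapiro-Wilk gate level (default 0.05).
#' @param min_quantified minimum fraction of quantified samples per group
#'   (default 0.6).
#' @return data.frame (`protein_id`, `log2fc`, `p`, `q`, `test_used`,
#'   `normal_all_groups`); q is the Benjamini-Hochberg adjusted p.
#' @export
adaptive_test <- function(mat, design, contrast = "mand_vs_sub_mean",
                          alpha_norm = 0.05, min_quantified = 0.6) {
  g <- contrast_groups(design, contrast)
  if (sum(g$a) < 3L || sum(g$b) < 3L)
    stop("adaptive_test: each contrast group needs n >= 3 (Shapiro-Wilk undefined below)")
  A <- mat[, g$a, drop = FALSE]
  B <- mat[, g$b, drop = FALSE]
  ok <- rowMeans(!is.na(A)) >= min_quantified &
        rowMeans(!is.na(B)) >= min_quantified
  A <- A[ok, , drop = FALSE]
  B <- B[ok, , drop = FALSE]
  n <- nrow(A)
  p <- numeric(n)
  fc <- numeric(n)
  test_used <- character(n)
  normal_all <- logical(n)
  for (i in seq_len(n)) {
    a <- A[i, ][!is.na(A[i, ])]
    b <- B[i, ][!is.na(B[i, ])]
    fc[i] <- mean(a) - mean(b)
    norm_ok <- function(x) {
      if (length(unique(x)) < 3L || sd(x) == 0) return(FALSE)
      shapiro.test(x)$p.value > alpha_norm
    }
    normal_all[i] <- norm_ok(a) && norm_ok(b)
    if (normal_all[i]) {
      p[i] <- t.test(a, b, var.equal = FALSE)$p.value
      test_used[i] <- "t"
    } else {
      ties <- any(duplicated(c(a, b)))
      exact <- length(a) <= 8L && length(b) <= 8L && !ties
      p[i] <- suppressWarnings(
        wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
      test_used[i] <- "wilcoxon"
    }
  }
  data.frame(protein_id = rownames(A) %||% as.character(seq_len(n)),
             log2fc = fc, p = p, q = bh_adjust(p),
             test_used = test_used, normal_all_groups = normal_all,
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Produces q-values controlling the false discovery rate; `q >= p`
#' elementwise, `q <= 1`, monotone over the sorted p-values, invariant to
#' input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Remove proteins upregulated with age in both LN types
#'
#' Isolates age-independent regional differences: any protein with
#' `log2fc > fc_min` and `q <= q_max` in BOTH old-vs-young comparisons
#' (one per site) is removed from the site comparison.
#'
#' @param site_rows site-contrast result (from [adaptive_test()]).
#' @param age_rows_mand,age_rows_sub old-vs-young results for the
#'   mandibular and subiliac site; must cover the same protein universe as
#'   `site_rows`.
#' @param fc_min,q_max joint condition thresholds (defaults 0 and 0.05).
#' @return list with `rows` (filtered site rows) and `removed`
#'   (character vector of removed protein ids).
#' @export
age_independent_filter <- function(site_rows, age_rows_mand, age_rows_sub,
                                   fc_min = 0, q_max = 0.05) {
  ids <- sort(site_rows$protein_id)
  if (!identical(ids, sort(age_rows_mand$protein_id)) ||
      !identical(ids, sort(age_rows_sub$protein_id)))
    stop("age_independent_filter: protein universes differ between row sets")
  up <- function(rows) rows$protein_id[rows$log2fc > fc_min &
                                       rows$q <= q_max]
  removed <- intersect(up(age_rows_mand), up(age_rows_sub))
  list(rows = site_rows[!site_rows$protein_id %in% removed, , drop = FALSE],
       removed = removed)
}

#' Volcano table with fold-change categories
#'
#' Categories follow the conventional volcano highlighting: `strong` for
#' fold change >= 2 at q <= 0.05, `moderate` for fold change in [1.5, 2)
#' at q <= 0.05, `none` otherwise (fold = 2^|log2fc|).
#'
#' @param rows a differential result data.frame with `log2fc` and `q`.
#' @return data.frame (`protein_id`, `log2fc`, `neg_log10_q`, `fold`,
#'   `category`).
#' @export
volcano_table <- function(rows) {
  stopifnot(all(is.finite(rows$log2fc)), all(is.finite(rows$q)))
  fold <- 2^abs(rows$log2fc)
  cat_ <- ifelse(fold >= 2 & rows$q <= 0.05, "strong",
          ifelse(fold >= 1.5 & rows$q <= 0.05, "moderate", "none"))
  data.frame(protein_id = rows$protein_id, log2fc = rows$log2fc,
             neg_log10_q = -log10(pmax(rows$q, .Machine$double.xmin)),
             fold = round(fold, 2), category = cat_)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file path (tab-separated: name, description, ids...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample gene set enrichment scores
#'
#' Rank-based ssGSEA: per sample, proteins are ranked by abundance
#' (descending; average ranks for ties) and the enrichment score is the
#' sum of the running difference between the weighted in-set ECDF (weight
#' `rank^alpha`) and the uniform out-of-set ECDF. Scores are invariant
#' under strictly monotone transforms of a sample's abundances.
#'
#' @param mat proteins x samples log2 abundance matrix with rownames.
#' @param sets named list of character vectors (gene/protein ids);
#'   intersected with the measured ids, empty intersections are an error.
#' @param weight_alpha rank-weighting exponent (default 0.25).
#' @return list with `scores` (sets x samples matrix) and `zscores`
#'   (row-wise z-scored variant for visualization).
#' @export
ssgsea_scores <- function(mat, sets, weight_alpha = 0.25) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  ids <- rownames(mat)
  sets <- lapply(sets, intersect, y = ids)
  if (any(lengths(sets) == 0L))
    stop("ssgsea_scores: gene set(s) with empty intersection: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  S <- matrix(NA_real_, length(sets), ncol(mat),
              dimnames = list(names(sets), colnames(mat)))
  N <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j])            # ascending: top protein has rank N
    ord <- order(mat[, j], decreasing = TRUE)
    w <- r[ord]^weight_alpha       # descending walk, weight = rank^alpha
    for (s in seq_along(sets)) {
      inset <- ids[ord] %in% sets[[s]]
      ecdf_in <- cumsum(w * inset) / sum(w[inset])
      ecdf_out <- cumsum(!inset) / (N - sum(inset))
      S[s, j] <- sum(ecdf_in - ecdf_out)
    }
  }
  z <- t(scale(t(S)))
  list(scores = S, zscores = z)
}

#' Pre-ranked gene set enrichment with a permutation null
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment score on a
#' ranked statistic (weight `|t|`), with a null built from `nperm` random
#' gene sets of the same size. NES is the ES divided by the mean absolute
#' null ES of the same sign; p is the permutation p-value with the +1
#' correction.
#'
#' @param tstats named per-protein statistic (e.g. Welch t).
#' @param sets named list of character vectors.
#' @param nperm number of random-set permutations (>= 100).
#' @param seed integer seed (deterministic given seed).
#' @return data.frame (`set`, `size`, `es`, `nes`, `p`, `q`).
#' @export
preranked_gsea <- function(tstats, sets, nperm = 1000L, seed = 1L) {
  stopifnot(nperm >= 100L, !is.null(names(tstats)),
            !any(duplicated(names(tstats))))
  ids <- names(tstats)
  ord <- order(tstats, decreasing = TRUE)
  stat_sorted <- tstats[ord]
  ids_sorted <- ids[ord]
  N <- length(ids)
  es_for <- function(positions) {
    # positions: indices (into the sorted list) of set members
    hit <- logical(N)
    hit[positions] <- TRUE
    w <- abs(stat_sorted)
    denom <- sum(w[hit])
    p_hit <- cumsum(ifelse(hit, w, 0)) / if (denom > 0) denom else 1
    p_miss <- cumsum(!hit) / (N - sum(hit))
    dev <- p_hit - p_miss
    dev[which.max(abs(dev))]
  }
  sets <- lapply(sets, intersect, y = ids)
  if (any(lengths(sets) == 0L)) stop("preranked_gsea: empty set after intersection")
  if (any(lengths(sets) > N)) stop("preranked_gsea: set larger than universe")
  with_seed(seed, {
    res <- lapply(names(sets), function(nm) {
      sz <- length(sets[[nm]])
      if (sz == N) {
        return(data.frame(set = nm, size = sz, es = 0, nes = 0, p = 1))
      }
      es <- es_for(which(ids_sorted %in% sets[[nm]]))
      null_es <- vapply(seq_len(nperm), function(i)
        es_for(sample.int(N, sz)), numeric(1))
      same_sign <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
      pval <- (1 + sum(abs(null_es) >= abs(es))) / (1 + nperm)
      data.frame(set = nm, size = sz, es = es, nes = nes, p = pval)
    })
    out <- do.call(rbind, res)
    out$q <- bh_adjust(out$p)
    out
  })
}

#' Group comparison of per-sample enrichment scores
#'
#' Wilcoxon rank-sum tests of ssGSEA scores between the two levels of a
#' design factor, per set, with Benjamini-Hochberg correction across sets.
#'
#' @param scores sets x samples score matrix (from [ssgsea_scores()]).
#' @param design design data.frame aligned with the score columns.
#' @param factor_name design column with exactly two levels.
#' @return data.frame (`set`, `p`, `q`).
#' @export
group_test_scores <- function(scores, design, factor_name = "site") {
  lev <- unique(design[[factor_name]])
  if (length(lev) != 2L)
    stop("group_test_scores: factor must have exactly two levels")
  a <- design[[factor_name]] == lev[1]
  if (sum(a) < 2L || sum(!a) < 2L)
    stop("group_test_scores: need >= 2 samples per level")
  p <- apply(scores, 1, function(row)
    compare_groups(row[a], row[!a])$p)
  data.frame(set = rownames(scores), p = p, q = bh_adjust(p),
             row.names = NULL)
}

#' Hypergeometric over-representation test against user-supplied sets
#'
#' For a selected protein list (e.g. significantly more abundant
#' proteins), tests each gene set for over-representation relative to the
#' measured universe.
#'
#' @param selected character vector of selected ids.
#' @param universe character vector of all measured ids.
#' @param sets named list of character vectors.
#' @return data.frame (`set`, `overlap`, `size`, `expected`, `p`, `q`).
#' @export
overrepresentation_test <- function(selected, universe, sets) {
  selected <- intersect(selected, universe)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(selected, s))
    p <- phyper(ov - 1, length(s), length(universe) - length(s),
                length(selected), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, size = length(s),
               expected = length(s) * length(selected) / length(universe),
               p = p)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Total-abundance normalization
#'
#' Emulates normalization to total protein amount: scales each sample
#' (column) of a linear-scale abundance matrix so all column sums match
#' the mean column sum, the step applied before log2 transformation.
#'
#' @param mat_linear proteins x samples linear-scale abundances (>= 0).
#' @param log2_transform also return log2 values (default TRUE); zeros
#'   become NA (not quantified).
#' @return normalized matrix (log2 scale when `log2_transform`).
#' @export
normalize_total <- function(mat_linear, log2_transform = TRUE) {
  cs <- colSums(mat_linear, na.rm = TRUE)
  if (any(cs <= 0)) stop("normalize_total: non-positive column sum")
  out <- sweep(mat_linear, 2, cs / mean(cs), "/")
  if (log2_transform) {
    out[out <= 0] <- NA
    out <- log2(out)
  }
  out
}
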