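#' Generate a synthetic methylation cohort with planted structure
#'
#' Emulates the statistical structure the downstream analysis assumes: a
#' samples-by-CpG matrix on a continuous normalized (M-value-like) scale with
#' i.i.d. Gaussian baseline noise, a set of aging-marker sites whose mean
#' increases monotonically with age, per-disease marker sites with an
#' additive mean shift in that disease's samples, an inflated aging slope in
#' disease samples (planted accelerated aging), additive per-cohort batch
#' offsets, and entries missing completely at random. Young ages are drawn
#' uniformly on 20..50 years, all other groups on 51..90.
#'
#' Defaults mirror the study conditions: group sizes 366 young, 442 aged
#' controls, 128 AD, 36 PD, 42 PSP and 123 FTD.
#'
#' @param n_young,n_old counts of young and aged healthy samples.
#' @param n_per_disease named integer vector of disease sample counts.
#' @param n_cpg number of CpG columns.
#' @param n_aging_markers number of planted age-associated sites.
#' @param n_disease_markers planted marker sites per disease (disjoint from
#'   aging markers and across diseases).
#' @param aging_effect standardized mean shift per decade of age at aging
#'   marker sites.
#' @param disease_effect standardized mean shift at disease marker sites in
#'   that disease's samples.
#' @param accel_factor multiplier on the aging slope in disease samples (the
#'   planted accelerated-aging pattern).
#' @param n_cohorts number of cohorts carrying batch offsets (default 4: a
#'   pooled multi-cohort design whose centred batch span is three
#'   directions, the structure the three-component SVD correction step is
#'   built to remove).
#' @param batch_sd per-site SD of the per-cohort additive offset vector;
#'   the default 1 emulates platform-scale heterogeneity comparable to the
#'   assay noise, the structure the SVD correction step removes.
#' @param missing_frac fraction of entries set missing at random, in `[0,1)`.
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return A list with elements `dataset` (a [methyl_dataset()]) and `truth`
#'   (ground-truth record: planted marker IDs, batch offsets, seed).
#' @export
generate_dataset <- function(n_young = 366, n_old = 442,
                             n_per_disease = c(AD = 128, PD = 36,
                                               PSP = 42, FTD = 123),
                             n_cpg = 2000, n_aging_markers = 40,
                             n_disease_markers = 20, aging_effect = 0.5,
                             disease_effect = 0.5, accel_factor = 1.5,
                             n_cohorts = 4, batch_sd = 1,
                             missing_frac = 0.05, seed = 1L) {
  if (missing_frac >= 1 || missing_frac < 0)
    stop("missing_frac must lie in [0, 1)")
  if (n_young < 1 || n_old < 1 || any(n_per_disease < 1) ||
      n_cpg < 1 || n_aging_markers < 1 || n_disease_markers < 1)
    stop("all counts must be >= 1")
  if (n_aging_markers + length(n_per_disease) * n_disease_markers > n_cpg)
    stop("planted markers exceed the number of CpG sites")
  if (is.null(names(n_per_disease)))
    stop("n_per_disease must be a named vector")

  set.seed(seed)
  groups <- c(rep("young", n_young), rep("control", n_old),
              rep(names(n_per_disease), n_per_disease))
  n <- length(groups)
  age <- integer(n)
  age[groups == "young"] <- sample(20:50, n_young, replace = TRUE)
  age[groups != "young"] <- sample(51:90, n - n_young, replace = TRUE)

  site_ids <- sprintf("cg%06d", seq_len(n_cpg))
  sample_ids <- sprintf("s%04d", seq_len(n))
  values <- matrix(rnorm(n * n_cpg), n, n_cpg,
                   dimnames = list(sample_ids, site_ids))

  marker_pool <- sample(n_cpg, n_aging_markers +
                          length(n_per_disease) * n_disease_markers)
  aging_idx <- marker_pool[seq_len(n_aging_markers)]
  disease_idx <- split(
    marker_pool[-seq_len(n_aging_markers)],
    rep(names(n_per_disease), each = n_disease_markers)
  )

  # monotone age effect, inflated in disease samples
  slope_mult <- ifelse(groups %in% DISEASE_GROUPS, accel_factor, 1)
  aging_signal <- aging_effect * (age - 50) / 10 * slope_mult
  values[, aging_idx] <- values[, aging_idx] + aging_signal

  for (d in names(disease_idx)) {
    rows <- groups == d
    values[rows, disease_idx[[d]]] <-
      values[rows, disease_idx[[d]]] + disease_effect
  }

  # per-cohort, per-site offset vectors (platform/batch heterogeneity)
  cohort <- sample(n_cohorts, n, replace = TRUE)
  offsets <- matrix(rnorm(n_cohorts * n_cpg, 0, batch_sd), n_cohorts, n_cpg)
  values <- values + offsets[cohort, , drop = FALSE]

  if (missing_frac > 0) {
    values[runif(n * n_cpg) < missing_frac] <- NA_real_
  }

  meta <- data.frame(sample_id = sample_ids, age = age, group = groups,
                     split = "unassigned", cohort = cohort,
                     stringsAsFactors = FALSE)
  truth <- list(
    aging_marker_ids = site_ids[aging_idx],
    disease_marker_ids = lapply(disease_idx, function(i) site_ids[i]),
    signflip_pairs = NULL,
    enriched_set_name = NULL,
    batch_offsets = offsets,
    cohort = cohort,
    seed = seed
  )
  list(dataset = methyl_dataset(values, meta), truth = truth)
}

#' Plant CpG pairs whose aging-driven correlation flips sign in disease
#'
#' Rewrites pairs of pure-noise columns so that each pair correlates at about
#' `+rho` within the healthy aged samples and about `-rho` within disease
#' samples. Both sites load on a shared latent aging axis (standardized age
#' over the aged samples); in disease samples the second site's loading is
#' negated. Because the co-methylation is carried by the aging axis, the
#' marginal correlation and the aging-score-conditioned partial correlation
#' separate (`r - pr` is `+rho` in controls and `-rho` in disease), which is
#' precisely the differential-edge signature the network stage retains.
#' These pairs are the ground truth for the network recovery tests.
#'
#' @param dataset a `methyl_dataset`.
#' @param truth the matching ground-truth record from [generate_dataset()].
#' @param n_pairs number of pairs to plant.
#' @param rho target absolute correlation, in `(0, 1)`.
#' @param seed integer seed.
#' @return A list `dataset`, `truth` with the pair list appended to
#'   `truth$signflip_pairs` and the disease-negated member sites recorded in
#'   `truth$signflip_flipped`. Note that because all planted sites share the
#'   aging axis, any pair of one unflipped and one flipped site is a
#'   structural sign-flip relation; recovery bookkeeping should treat those
#'   cross pairs as true positives.
#' @export
plant_signflip_pairs <- function(dataset, truth, n_pairs, rho, seed = 1L) {
  if (n_pairs == 0) return(list(dataset = dataset, truth = truth))
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  used <- c(truth$aging_marker_ids, unlist(truth$disease_marker_ids),
            as.vector(truth$signflip_pairs))
  noise <- setdiff(colnames(dataset$values), used)
  if (length(noise) < 2 * n_pairs)
    stop("not enough pure-noise sites to plant ", n_pairs, " pairs")

  set.seed(seed)
  picked <- sample(noise, 2 * n_pairs)
  pairs <- matrix(picked, ncol = 2,
                  dimnames = list(NULL, c("site_a", "site_b")))
  grp <- dataset$meta$group
  n <- nrow(dataset$values)
  old <- grp != "young"
  f <- (dataset$meta$age - mean(dataset$meta$age[old])) /
    sd(dataset$meta$age[old])
  sgn <- ifelse(grp %in% DISEASE_GROUPS, -1, 1)
  for (i in seq_len(n_pairs)) {
    e <- matrix(rnorm(2 * n), n, 2)
    x <- sqrt(rho) * f + sqrt(1 - rho) * e[, 1]
    y <- sgn * sqrt(rho) * f + sqrt(1 - rho) * e[, 2]
    # young samples are outside the network analysis: plain unit noise,
    # so the planted pairs carry no young-vs-aged class signal
    x[!old] <- rnorm(sum(!old))
    y[!old] <- rnorm(sum(!old))
    dataset$values[, pairs[i, ]] <- cbind(x, y)
  }
  truth$signflip_pairs <- rbind(truth$signflip_pairs, pairs)
  # site_b loadings are the ones negated in disease; any (unflipped,
  # flipped) pair of planted sites is therefore a structural sign-flip
  # relation, not only the canonical pairs above
  truth$signflip_flipped <- c(truth$signflip_flipped, pairs[, "site_b"])
  list(dataset = dataset, truth = truth)
}

#' Generate a CpG-to-gene annotation and gene-set collection
#'
#' Produces a surjective CpG-to-gene map (every gene has at least one CpG),
#' `n_sets` random gene sets of size `set_size`, and one planted enriched set
#' containing the genes of the planted disease markers (padded with random
#' genes up to `set_size` if needed).
#'
#' @param n_cpg number of CpG sites (IDs match [generate_dataset()] naming).
#' @param n_genes number of genes, at most `n_cpg`.
#' @param n_sets number of random background sets.
#' @param set_size genes per random set, at most `n_genes`.
#' @param truth optional ground truth; its disease markers define the
#'   planted enriched set.
#' @param seed integer seed.
#' @return A list: `annotation` (data.frame `cpg_id`, `gene`), `genesets`
#'   (named list of gene vectors), `universe`, `enriched_set_name`.
#' @export
generate_annotation_and_genesets <- function(n_cpg, n_genes, n_sets,
                                             set_size, truth = NULL,
                                             seed = 1L) {
  if (n_genes > n_cpg) stop("n_genes must not exceed n_cpg")
  if (set_size > n_genes) stop("set_size must not exceed n_genes")
  set.seed(seed)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  # surjective: a permutation recycled over the CpGs, then shuffled
  gene_of <- sample(rep_len(sample(genes), n_cpg))
  annotation <- data.frame(cpg_id = sprintf("cg%06d", seq_len(n_cpg)),
                           gene = gene_of, stringsAsFactors = FALSE)

  sets <- lapply(seq_len(n_sets), function(i) sort(sample(genes, set_size)))
  names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))

  enriched_name <- "PLANTED_DISEASE_SET"
  planted_cpgs <- unlist(truth$disease_marker_ids)
  planted_genes <- unique(annotation$gene[annotation$cpg_id %in% planted_cpgs])
  if (length(planted_genes) < set_size) {
    planted_genes <- union(
      planted_genes,
      sample(setdiff(genes, planted_genes),
             set_size - length(planted_genes))
    )
  }
  sets[[enriched_name]] <- sort(planted_genes)

  list(annotation = annotation, genesets = sets, universe = genes,
       enriched_set_name = enriched_name)
}
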