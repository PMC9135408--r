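# Synthetic-data generators with planted ground truth. Every downstream
# stage of the package can be exercised, and its recovery measured,
# against data whose lost/retained/gained structure, class overlaps,
# contaminants, correlations and screen hits are known by construction.
#
# One global seed is expanded into per-stream substream seeds
# (substream_seed) so that adding a generator call does not perturb the
# draws of the others; identical seed + parameters give byte-identical
# outputs.

#' Generate a genome specification
#'
#' @param n_chroms Number of chromosomes (>= 1), named `chr1..chrN`.
#' @param length_per_chrom Length of each chromosome in bp (>= 1).
#' @param seed Integer seed (kept for interface symmetry; the genome is
#'   fully determined by the arguments).
#' @return A [genome_spec()].
#' @export
generate_genome <- function(n_chroms, length_per_chrom, seed = 1) {
  check_scalar_number(n_chroms, "n_chroms", lower = 1, integer = TRUE)
  check_scalar_number(length_per_chrom, "length_per_chrom", lower = 1,
                      integer = TRUE)
  genome_spec(paste0("chr", seq_len(n_chroms)),
              rep(length_per_chrom, n_chroms))
}

# Rejection-sampled placement of n peak start positions such that starts
# on the same chromosome are >= width + min_gap apart (no overlap, with a
# safety margin for downstream jitter). Errors out when the placement cap
# is exceeded rather than silently overlapping.
place_peaks <- function(genome, n, width, min_gap = width,
                        forbidden = NULL, max_candidates = NULL) {
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric()))
  lens <- genome$chrom_lengths
  if (all(lens < width))
    stop_("peak width %d exceeds every chromosome length", width)
  sep <- width + min_gap
  starts <- lapply(genome$chrom_names, function(ch) numeric(0))
  names(starts) <- genome$chrom_names
  if (!is.null(forbidden)) {
    for (ch in names(forbidden))
      starts[[ch]] <- sort(forbidden[[ch]])
  }
  placed_chrom <- character(n)
  placed_start <- numeric(n)
  placed <- 0L
  candidates_used <- 0L
  cap <- max_candidates %||% max(1000L, 200L * n)
  probs <- lens / sum(lens)
  while (placed < n) {
    need <- n - placed
    chunk <- max(2L * need, 16L)
    if (candidates_used + chunk > cap)
      stop_(paste0("could not place %d non-overlapping peaks of width %d ",
                   "on this genome (placement-attempt cap reached)"),
            n, width)
    candidates_used <- candidates_used + chunk
    ch <- sample(genome$chrom_names, chunk, replace = TRUE, prob = probs)
    s <- floor(runif(chunk, 0, pmax(lens[ch] - width + 1, 1)))
    for (i in seq_len(chunk)) {
      ss <- starts[[ch[i]]]
      j <- findInterval(s[i], ss)
      if (j >= 1 && s[i] - ss[j] < sep) next
      if (j < length(ss) && ss[j + 1] - s[i] < sep) next
      starts[[ch[i]]] <- append(ss, s[i], after = j)
      placed <- placed + 1L
      placed_chrom[placed] <- ch[i]
      placed_start[placed] <- s[i]
      if (placed == n) break
    }
  }
  data.frame(chrom = placed_chrom, start = placed_start,
             stringsAsFactors = FALSE)
}

#' Parameters for planted two-condition peak sets
#'
#' @param n_peaks Total number of planted binding sites.
#' @param peak_width Peak width in bp.
#' @param frac_lost,frac_retained,frac_gained Class proportions; must sum
#'   to 1 (counts are produced by largest-remainder apportionment so they
#'   sum exactly to `n_peaks`).
#' @param class_overlap Optional named proportions (names among `NARBS`,
#'   `TARBS`, `metARBS`, `UARBS`, summing to <= 1) of sites planted
#'   inside each ARBS class; the remainder are OTHER.
#' @param pioneer_overlap Optional proportion of sites planted inside a
#'   pioneer-factor reference set (applied per taxonomy class).
#' @param retained_jitter Maximum absolute shift (bp) applied to the
#'   treated copy of a retained site (default `peak_width %/% 4`; always
#'   small enough that the two copies overlap).
#' @return A `cistrome_params` list.
#' @export
cistrome_params <- function(n_peaks = 1000, peak_width = 200,
                            frac_lost = 0.2, frac_retained = 0.5,
                            frac_gained = 0.3, class_overlap = NULL,
                            pioneer_overlap = NULL,
                            retained_jitter = NULL) {
  check_scalar_number(n_peaks, "n_peaks", lower = 0, integer = TRUE)
  check_scalar_number(peak_width, "peak_width", lower = 1, integer = TRUE)
  check_proportion(frac_lost, "frac_lost")
  check_proportion(frac_retained, "frac_retained")
  check_proportion(frac_gained, "frac_gained")
  if (abs(frac_lost + frac_retained + frac_gained - 1) > 1e-9)
    stop_("frac_lost + frac_retained + frac_gained must equal 1")
  if (!is.null(class_overlap)) {
    if (is.null(names(class_overlap)) ||
        !all(names(class_overlap) %in% ARBS_CLASSES))
      stop_("class_overlap names must be ARBS classes")
    for (v in class_overlap) check_proportion(v, "class_overlap")
    if (sum(class_overlap) > 1 + 1e-9)
      stop_("class_overlap proportions must sum to <= 1")
  }
  if (!is.null(pioneer_overlap))
    check_proportion(pioneer_overlap, "pioneer_overlap")
  retained_jitter <- retained_jitter %||% (peak_width %/% 4)
  check_scalar_number(retained_jitter, "retained_jitter", lower = 0,
                      upper = max(peak_width - 1, 0), integer = TRUE)
  structure(list(n_peaks = n_peaks, peak_width = peak_width,
                 frac_lost = frac_lost, frac_retained = frac_retained,
                 frac_gained = frac_gained, class_overlap = class_overlap,
                 pioneer_overlap = pioneer_overlap,
                 retained_jitter = retained_jitter),
            class = "cistrome_params")
}

#' Generate two-condition peak sets with planted differential classes
#'
#' Plants `n_peaks` well-separated binding sites and assigns each a
#' differential class: *lost* sites appear only in the control set,
#' *gained* only in the treated set, and *retained* sites appear in both
#' (the treated copy jittered by at most `retained_jitter` bp so the two
#' copies still overlap). Optionally also plants disjoint ARBS-class
#' reference sets and a pioneer-factor reference set covering stated
#' fractions of the sites.
#'
#' @param genome A [genome_spec()].
#' @param params A [cistrome_params()].
#' @param seed Integer seed.
#' @return List with peak sets `control` and `treated`, a `truth`
#'   data.frame (`site`, `chrom`, `start`, `end`, `class`, `arbs_class`,
#'   `in_pioneer`), `class_sets` (named list of `GRanges` or `NULL`),
#'   `pioneer` (`GRanges` or `NULL`), planted count summaries
#'   `planted_counts`, `planted_pioneer_by_class`, and `params`.
#' @export
generate_condition_peaks <- function(genome, params = cistrome_params(),
                                     seed = 1) {
  stopifnot(inherits(genome, "genome_spec"),
            inherits(params, "cistrome_params"))
  w <- params$peak_width
  n <- params$n_peaks
  if (n == 0) {
    empty <- peak_set(character(), numeric(), numeric(), genome = genome)
    return(list(control = empty, treated = empty,
                truth = data.frame(), class_sets = NULL, pioneer = NULL,
                planted_counts = c(lost = 0L, retained = 0L, gained = 0L),
                planted_pioneer_by_class = NULL, params = params))
  }
  with_seed(substream_seed(seed, 11L), {
    anchors <- place_peaks(genome, n, w, min_gap = w)
    counts <- apportion(n, c(lost = params$frac_lost,
                             retained = params$frac_retained,
                             gained = params$frac_gained))
    cls <- sample(rep(names(counts), counts))
    truth <- data.frame(site = sprintf("site%05d", seq_len(n)),
                        chrom = anchors$chrom, start = anchors$start,
                        end = anchors$start + w, class = cls,
                        stringsAsFactors = FALSE)

    ctl <- truth$class %in% c("lost", "retained")
    control <- peak_set(truth$chrom[ctl], truth$start[ctl], truth$end[ctl],
                        name = truth$site[ctl], label = "control",
                        genome = genome)
    ret <- truth$class == "retained"
    jit <- if (params$retained_jitter > 0)
      sample(seq(-params$retained_jitter, params$retained_jitter), sum(ret),
             replace = TRUE) else rep(0L, sum(ret))
    t_start <- truth$start
    t_start[ret] <- pmin(pmax(t_start[ret] + jit, 0),
                         genome$chrom_lengths[truth$chrom[ret]] - w)
    trt <- truth$class %in% c("retained", "gained")
    treated <- peak_set(truth$chrom[trt], t_start[trt], t_start[trt] + w,
                        name = truth$site[trt], label = "treated",
                        genome = genome)

    class_sets <- NULL
    truth$arbs_class <- "OTHER"
    if (!is.null(params$class_overlap)) {
      fr <- c(params$class_overlap, OTHER = 1 - sum(params$class_overlap))
      k <- apportion(n, fr)
      assign_cls <- sample(rep(names(k), k))
      truth$arbs_class <- assign_cls
      class_sets <- lapply(names(params$class_overlap), function(cc) {
        sel <- assign_cls == cc
        peak_set(truth$chrom[sel], truth$start[sel], truth$end[sel],
                 label = cc, genome = genome)
      })
      names(class_sets) <- names(params$class_overlap)
    }

    pioneer <- NULL
    pio_by_class <- NULL
    truth$in_pioneer <- FALSE
    if (!is.null(params$pioneer_overlap)) {
      classes <- unique(truth$arbs_class)
      sel_all <- logical(n)
      pio_by_class <- setNames(integer(length(classes)), classes)
      for (cc in classes) {
        idx <- which(truth$arbs_class == cc)
        k_c <- apportion(length(idx), c(inside = params$pioneer_overlap,
                                        outside = 1 - params$pioneer_overlap))
        pio_by_class[cc] <- k_c[["inside"]]
        sel_all[idx[sample.int(length(idx), k_c[["inside"]])]] <- TRUE
      }
      truth$in_pioneer <- sel_all
      pioneer <- peak_set(truth$chrom[sel_all], truth$start[sel_all],
                          truth$end[sel_all], label = "pioneer",
                          genome = genome)
    }
    list(control = control, treated = treated, truth = truth,
         class_sets = class_sets, pioneer = pioneer,
         planted_counts = counts,
         planted_pioneer_by_class = pio_by_class, params = params)
  })
}

#' Generate a library of reference cistromes with planted co-binding
#'
#' Places one designated pioneer-factor peak set, then for every other
#' factor plants `floor(pioneer_overlap * peaks_per_factor)` peaks
#' exactly inside (randomly chosen) pioneer peaks and the remainder in
#' pioneer-free territory, so each factor's true overlap fraction with
#' the pioneer is known. No two peaks within a factor's set overlap.
#'
#' @param genome A [genome_spec()].
#' @param n_factors Number of factors including the pioneer (>= 1).
#' @param peaks_per_factor Peaks per factor.
#' @param pioneer_overlap Proportion of each non-pioneer factor's peaks
#'   planted inside pioneer peaks; scalar, or a named vector over the
#'   non-pioneer factor labels.
#' @param peak_width Peak width in bp.
#' @param pioneer_factor Label of the pioneer entry (default `FOXA1`).
#' @param seed Integer seed.
#' @return List with `library` (named list of peak sets, pioneer first),
#'   `pioneer_factor` and `truth` (data.frame `factor`,
#'   `planted_overlap`).
#' @export
generate_cistrome_library <- function(genome, n_factors = 10,
                                      peaks_per_factor = 100,
                                      pioneer_overlap = 0.6,
                                      peak_width = 300,
                                      pioneer_factor = "FOXA1", seed = 1) {
  stopifnot(inherits(genome, "genome_spec"))
  check_scalar_number(n_factors, "n_factors", lower = 1, integer = TRUE)
  check_scalar_number(peaks_per_factor, "peaks_per_factor", lower = 1,
                      integer = TRUE)
  check_scalar_number(peak_width, "peak_width", lower = 1, integer = TRUE)
  others <- if (n_factors > 1)
    sprintf("TF%02d", seq_len(n_factors - 1)) else character(0)
  if (length(pioneer_overlap) == 1 && is.null(names(pioneer_overlap))) {
    pioneer_overlap <- setNames(rep(pioneer_overlap, length(others)), others)
  } else if (!setequal(names(pioneer_overlap), others)) {
    stop_("named pioneer_overlap must cover exactly the non-pioneer factors")
  }
  for (v in pioneer_overlap) check_proportion(v, "pioneer_overlap")
  with_seed(substream_seed(seed, 13L), {
    pio <- place_peaks(genome, peaks_per_factor, peak_width,
                       min_gap = peak_width)
    pioneer_set <- peak_set(pio$chrom, pio$start, pio$start + peak_width,
                            label = pioneer_factor, genome = genome)
    forbidden <- split(pio$start, pio$chrom)
    library <- c(setNames(list(pioneer_set), pioneer_factor),
                 lapply(others, function(f) {
                   k <- floor(pioneer_overlap[[f]] * peaks_per_factor)
                   inside_idx <- sample(nrow(pio), k)
                   outside <- place_peaks(genome, peaks_per_factor - k,
                                          peak_width, min_gap = 1,
                                          forbidden = forbidden)
                   peak_set(c(pio$chrom[inside_idx], outside$chrom),
                            c(pio$start[inside_idx], outside$start),
                            c(pio$start[inside_idx], outside$start) +
                              peak_width,
                            label = f, genome = genome)
                 }))
    names(library) <- c(pioneer_factor, others)
    truth <- data.frame(
      factor = names(library),
      planted_overlap = c(1, floor(pioneer_overlap[others] *
                                     peaks_per_factor) / peaks_per_factor),
      stringsAsFactors = FALSE)
    list(library = library, pioneer_factor = pioneer_factor, truth = truth)
  })
}

#' Parameters for planted RIME experiments
#'
#' Defaults describe a two-condition single-bait experiment whose
#' differential classes match the headline study structure: 506
#' bait-specific interactors splitting into 77 lost, 222 retained and
#' 207 gained, over 2 replicates, with 50 control-IP contaminants.
#'
#' @param baits Character vector of bait labels.
#' @param control_bait Label of the negative-control IP (tag-only /
#'   luciferase pulldown) used for background subtraction.
#' @param conditions One or two condition labels; with two, differential
#'   classes are planted.
#' @param n_replicates Replicates per bait and condition.
#' @param n_shared Number of interactors shared by all baits (ignored
#'   when `region_counts` is given).
#' @param n_specific_per_bait Number of interactors specific to each
#'   bait (ignored when `region_counts` is given).
#' @param region_counts Optional named list/vector giving the number of
#'   interactors for arbitrary bait combinations, e.g.
#'   `c("CREB5&FOXA1" = 335, "CREB5&CREB3&FOXA1" = 169)`; names join
#'   bait labels with `&`. Overrides `n_shared` /
#'   `n_specific_per_bait`.
#' @param n_contaminants Background proteins precipitated by every IP
#'   including the control.
#' @param frac_lost,frac_retained,frac_gained Differential-class
#'   proportions across conditions (must sum to 1; two-condition case).
#' @param detection_prob Per-replicate detection probability of a
#'   planted protein.
#' @param count_mean Mean unique-peptide count of a detected protein.
#' @param count_dispersion Negative-binomial dispersion of the
#'   gamma-Poisson count model. The gamma mixture acts at the protein
#'   level (one latent abundance per protein, shared by every IP that
#'   detects it), so dispersion > 0 also sets the count correlation
#'   between baits with shared interactors; 0 gives independent Poisson
#'   counts.
#' @param self_peptide_mean Mean unique-peptide count of each bait's own
#'   protein in its IP; scalar or named by bait (default: 8).
#' @return A `rime_params` list.
#' @export
rime_params <- function(baits = "CREB5", control_bait = "LUCIFERASE",
                        conditions = c("control", "enzalutamide"),
                        n_replicates = 2, n_shared = 0,
                        n_specific_per_bait = 506, region_counts = NULL,
                        n_contaminants = 50, frac_lost = 77 / 506,
                        frac_retained = 222 / 506, frac_gained = 207 / 506,
                        detection_prob = 1, count_mean = 4,
                        count_dispersion = 0.3, self_peptide_mean = 8) {
  stopifnot(length(baits) >= 1, length(conditions) %in% 1:2)
  if (control_bait %in% baits)
    stop_("control_bait must differ from the baits")
  check_scalar_number(n_replicates, "n_replicates", lower = 1,
                      integer = TRUE)
  check_scalar_number(n_shared, "n_shared", lower = 0, integer = TRUE)
  check_scalar_number(n_specific_per_bait, "n_specific_per_bait", lower = 0,
                      integer = TRUE)
  check_scalar_number(n_contaminants, "n_contaminants", lower = 0,
                      integer = TRUE)
  check_proportion(detection_prob, "detection_prob")
  check_scalar_number(count_mean, "count_mean", lower = 1)
  check_scalar_number(count_dispersion, "count_dispersion", lower = 0)
  if (length(conditions) == 2 &&
      abs(frac_lost + frac_retained + frac_gained - 1) > 1e-9)
    stop_("frac_lost + frac_retained + frac_gained must equal 1")
  if (!is.null(region_counts)) {
    region_counts <- unlist(region_counts)
    for (r in names(region_counts)) {
      members <- strsplit(r, "&", fixed = TRUE)[[1]]
      if (!all(members %in% baits))
        stop_("region '%s' names a bait not in 'baits'", r)
    }
  }
  if (length(self_peptide_mean) == 1 && is.null(names(self_peptide_mean)))
    self_peptide_mean <- setNames(rep(self_peptide_mean, length(baits)),
                                  baits)
  structure(list(baits = baits, control_bait = control_bait,
                 conditions = conditions, n_replicates = n_replicates,
                 n_shared = n_shared,
                 n_specific_per_bait = n_specific_per_bait,
                 region_counts = region_counts,
                 n_contaminants = n_contaminants, frac_lost = frac_lost,
                 frac_retained = frac_retained, frac_gained = frac_gained,
                 detection_prob = detection_prob, count_mean = count_mean,
                 count_dispersion = count_dispersion,
                 self_peptide_mean = self_peptide_mean),
            class = "rime_params")
}

# Gamma-Poisson (negative binomial) unique-peptide counts with the
# mixture at the protein level: each protein draws one latent rate
# lambda ~ Gamma(1/dispersion, mean * dispersion), and every IP /
# replicate containing the protein draws Poisson(lambda), floored at 1.
# Marginally the counts are NB(mean, dispersion); the shared latent rate
# models protein-specific abundance/detectability, which is what makes
# the profiles of baits with shared interactors correlate.
draw_protein_rates <- function(n, mean, dispersion) {
  if (n == 0) return(numeric(0))
  if (dispersion <= 0) return(rep(mean, n))
  stats::rgamma(n, shape = 1 / dispersion, scale = mean * dispersion)
}

#' Generate a RIME experiment with planted interaction structure
#'
#' Builds a peptide-record table for one or more baits plus a control IP
#' with known ground truth: which proteins are contaminants (present in
#' the control IP), which bait combinations each interactor belongs to,
#' and — for two-condition experiments — each interactor's
#' lost/retained/gained class. Unique-peptide counts follow a
#' protein-level gamma-Poisson model (see [rime_params()]); detection
#' per replicate is Bernoulli.
#'
#' @param params A [rime_params()].
#' @param seed Integer seed.
#' @return List with `records` (peptide records as from
#'   [read_rime_table()]), `truth` (data.frame `protein`, `category`,
#'   `region`, `class`) and `params`.
#' @export
generate_rime_experiment <- function(params = rime_params(), seed = 1) {
  stopifnot(inherits(params, "rime_params"))
  with_seed(substream_seed(seed, 17L), {
    baits <- params$baits
    two_cond <- length(params$conditions) == 2
    regions <- params$region_counts
    if (is.null(regions)) {
      regions <- c(
        if (params$n_shared > 0 && length(baits) > 1)
          setNames(params$n_shared, paste(baits, collapse = "&")),
        setNames(rep(params$n_specific_per_bait, length(baits)), baits))
      regions <- regions[regions > 0]
    }
    n_int <- sum(regions)
    truth <- data.frame(
      protein = sprintf("INT%04d", seq_len(n_int)),
      category = "interactor",
      region = rep(names(regions), regions),
      class = NA_character_,
      stringsAsFactors = FALSE)
    if (two_cond && n_int > 0) {
      counts <- apportion(n_int, c(lost = params$frac_lost,
                                   retained = params$frac_retained,
                                   gained = params$frac_gained))
      truth$class <- sample(rep(names(counts), counts))
    } else if (n_int > 0) {
      truth$class <- "retained"
    }
    if (params$n_contaminants > 0) {
      truth <- rbind(truth, data.frame(
        protein = sprintf("CONT%03d", seq_len(params$n_contaminants)),
        category = "contaminant", region = "", class = NA_character_,
        stringsAsFactors = FALSE))
    }
    truth <- rbind(truth, data.frame(
      protein = baits, category = "bait_self", region = baits,
      class = "retained", stringsAsFactors = FALSE))

    cond_for_class <- function(cl) {
      if (!two_cond) return(list(params$conditions))
      switch(cl,
             lost = list(params$conditions[1]),
             retained = list(params$conditions),
             gained = list(params$conditions[2]),
             list(params$conditions))
    }
    grid <- list()
    all_ips <- c(baits, params$control_bait)
    for (i in seq_len(nrow(truth))) {
      prot <- truth$protein[i]
      cat_i <- truth$category[i]
      ips <- switch(cat_i,
                    contaminant = all_ips,
                    bait_self = truth$region[i],
                    strsplit(truth$region[i], "&", fixed = TRUE)[[1]])
      conds <- if (cat_i == "contaminant") list(params$conditions)
               else cond_for_class(truth$class[i])
      grid[[i]] <- expand.grid(bait = ips, condition = unlist(conds),
                               replicate = seq_len(params$n_replicates),
                               protein = prot, stringsAsFactors = FALSE)
    }
    grid <- do.call(rbind, grid)
    is_self <- grid$protein %in% baits & grid$bait == grid$protein
    detected <- runif(nrow(grid)) < params$detection_prob
    detected[is_self] <- TRUE  # the bait always pulls itself down
    grid <- grid[detected, , drop = FALSE]
    is_self <- grid$protein %in% baits & grid$bait == grid$protein
    rates <- setNames(draw_protein_rates(nrow(truth), params$count_mean,
                                         params$count_dispersion),
                      truth$protein)
    rates[baits] <- params$self_peptide_mean[baits]
    k <- pmax(rpois(nrow(grid), rates[grid$protein]), 1L)
    records <- data.frame(
      bait = rep(grid$bait, k),
      condition = rep(grid$condition, k),
      replicate = rep(grid$replicate, k),
      protein = rep(grid$protein, k),
      peptide = paste0(rep(grid$protein, k), ".p", sequence(k)),
      count = 1L + rpois(sum(k), 1),
      stringsAsFactors = FALSE)
    rownames(records) <- NULL
    list(records = records, truth = truth, params = params)
  })
}

#' Parameters for planted expression matrices
#'
#' @param n_genes Number of background genes (beyond signature + index).
#' @param n_samples Number of samples (default 208, a typical mCRPC
#'   expression cohort size).
#' @param signature_genes Labels of the planted signature genes.
#' @param index_gene Label of the index gene.
#' @param target_rho Planted Pearson correlation (on the latent normal
#'   scale) between index and each signature gene, in `[-1, 1]`; the
#'   recovered Spearman correlation is slightly attenuated
#'   (`6/pi * asin(rho/2)`).
#' @param noise_sd Standard deviation multiplier of the independent
#'   noise component (1 gives exactly `target_rho` on the latent scale).
#' @return An `expression_params` list.
#' @export
expression_params <- function(n_genes = 2000, n_samples = 208,
                              signature_genes = sprintf("SIG%03d", 1:50),
                              index_gene = "CREB5", target_rho = 0.6,
                              noise_sd = 1) {
  check_scalar_number(n_genes, "n_genes", lower = 0, integer = TRUE)
  check_scalar_number(n_samples, "n_samples", lower = 3, integer = TRUE)
  check_scalar_number(target_rho, "target_rho", lower = -1, upper = 1)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (index_gene %in% signature_genes)
    stop_("index gene must not be listed among the signature genes")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 signature_genes = unique(signature_genes),
                 index_gene = index_gene, target_rho = target_rho,
                 noise_sd = noise_sd),
            class = "expression_params")
}

#' Parameters for planted viability and dependency screens
#'
#' Defaults emulate a genome-scale ORF viability screen with one planted
#' treatment-specific hit (generating Z means +14.5 under treatment,
#' -1.3 in standard culture) and an RNAi dependency screen in which
#' three genes are strong dependencies only in the AR-positive cell-line
#' group.
#'
#' @param n_orfs Number of ORFs in the viability screen.
#' @param arms Two arm labels, control first.
#' @param hits Named list: gene -> `c(z_control, z_treated)` generating
#'   means.
#' @param hit_sd Noise SD around planted hit means.
#' @param n_dep_genes Number of genes in the dependency screen.
#' @param dep_genes Genes planted as group-specific dependencies.
#' @param group_sizes Named integer vector of cell lines per group.
#' @param dep_group Group in which `dep_genes` are dependencies.
#' @param dep_mean Generating mean dependency score of `dep_genes` in
#'   `dep_group` (negative = dependency, DEMETER convention).
#' @param nondep_mean Generating mean of `dep_genes` outside
#'   `dep_group` (slightly positive: planted non-dependence).
#' @param background_sd SD of background dependency scores.
#' @return A `screen_params` list.
#' @export
screen_params <- function(n_orfs = 2000,
                          arms = c("standard", "enzalutamide"),
                          hits = list(CREB5 = c(-1.3, 14.5)),
                          hit_sd = 0.3, n_dep_genes = 1000,
                          dep_genes = c("FOXA1", "TBX3", "NFIC"),
                          group_sizes = c(AR_positive = 4, AR_negative = 3,
                                          non_PC = 40),
                          dep_group = "AR_positive", dep_mean = -3,
                          nondep_mean = 0.25, background_sd = 0.5) {
  check_scalar_number(n_orfs, "n_orfs", lower = 1, integer = TRUE)
  stopifnot(length(arms) == 2, is.list(hits),
            all(lengths(hits) == 2), !is.null(names(group_sizes)),
            dep_group %in% names(group_sizes))
  check_scalar_number(n_dep_genes, "n_dep_genes", lower = 1, integer = TRUE)
  structure(list(n_orfs = n_orfs, arms = arms, hits = hits, hit_sd = hit_sd,
                 n_dep_genes = n_dep_genes, dep_genes = dep_genes,
                 group_sizes = group_sizes, dep_group = dep_group,
                 dep_mean = dep_mean, nondep_mean = nondep_mean,
                 background_sd = background_sd),
            class = "screen_params")
}

#' Generate planted expression, viability-screen and dependency data
#'
#' Expression: a latent standard-normal factor per sample drives the
#' index gene; each signature gene is
#' `rho * latent + sqrt(1 - rho^2) * noise_sd * N(0,1)`, then all latent
#' values are mapped through `10 * exp(.)` to TPM-like positive units (a
#' strictly monotone map, so Spearman correlations are preserved).
#' Viability screen: background Z ~ N(0,1) per arm; planted hits drawn
#' around their generating means. Dependency screen: background
#' `N(0, background_sd)`; planted dependency genes drawn around
#' `dep_mean` in `dep_group` and `nondep_mean` elsewhere.
#'
#' @param expr_params An [expression_params()].
#' @param scr_params A [screen_params()].
#' @param seed Integer seed.
#' @return List with `expression` (matrix genes x samples), `screen`
#'   (a [screen_matrix()] of Z-scores), `dependency` (a
#'   [screen_matrix()] with cell-line groups) and `truth`.
#' @export
generate_expression_and_screens <- function(expr_params = expression_params(),
                                            scr_params = screen_params(),
                                            seed = 1) {
  stopifnot(inherits(expr_params, "expression_params"),
            inherits(scr_params, "screen_params"))
  expression <- with_seed(substream_seed(seed, 19L), {
    ep <- expr_params
    z <- rnorm(ep$n_samples)
    sig <- t(vapply(ep$signature_genes, function(g)
      ep$target_rho * z +
        sqrt(max(1 - ep$target_rho^2, 0)) * ep$noise_sd * rnorm(ep$n_samples),
      numeric(ep$n_samples)))
    bg <- if (ep$n_genes > 0)
      matrix(rnorm(ep$n_genes * ep$n_samples), nrow = ep$n_genes,
             dimnames = list(sprintf("G%05d", seq_len(ep$n_genes)), NULL))
      else matrix(numeric(0), nrow = 0, ncol = ep$n_samples)
    m <- rbind(matrix(z, nrow = 1, dimnames = list(ep$index_gene, NULL)),
               sig, bg)
    colnames(m) <- sprintf("S%04d", seq_len(ep$n_samples))
    10 * exp(m)
  })
  screen <- with_seed(substream_seed(seed, 23L), {
    sp <- scr_params
    genes <- unique(c(names(sp$hits), sprintf("ORF%05d", seq_len(sp$n_orfs))))
    z <- matrix(rnorm(length(genes) * 2), ncol = 2,
                dimnames = list(genes, sp$arms))
    for (g in names(sp$hits))
      z[g, ] <- rnorm(2, mean = sp$hits[[g]], sd = sp$hit_sd)
    screen_matrix(z)
  })
  dependency <- with_seed(substream_seed(seed, 29L), {
    sp <- scr_params
    genes <- unique(c(sp$dep_genes, sprintf("DEP%05d",
                                            seq_len(sp$n_dep_genes))))
    lines <- unlist(lapply(names(sp$group_sizes), function(gp)
      sprintf("%s_%02d", gp, seq_len(sp$group_sizes[[gp]]))))
    groups <- setNames(rep(names(sp$group_sizes), sp$group_sizes), lines)
    d <- matrix(rnorm(length(genes) * length(lines), sd = sp$background_sd),
                nrow = length(genes), dimnames = list(genes, lines))
    in_dep <- groups[colnames(d)] == sp$dep_group
    for (g in sp$dep_genes) {
      d[g, in_dep] <- rnorm(sum(in_dep), sp$dep_mean, sp$background_sd)
      d[g, !in_dep] <- rnorm(sum(!in_dep), sp$nondep_mean, sp$background_sd)
    }
    screen_matrix(d, groups)
  })
  list(expression = expression, screen = screen, dependency = dependency,
       truth = list(index_gene = expr_params$index_gene,
                    signature_genes = expr_params$signature_genes,
                    target_rho = expr_params$target_rho,
                    screen_hits = scr_params$hits,
                    dep_genes = scr_params$dep_genes,
                    dep_group = scr_params$dep_group))
}

#' Write a labelled numeric matrix as TSV
#'
#' @param m Matrix with row names.
#' @param path Output path.
#' @param id_col Name of the first (row-label) column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
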