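#' @name synthetic_data
#' @title Seeded generators with known planted structure
#'
#' @description
#' Generators emulating the statistical structure of a fibrosis miRNome
#' study: (i) a biopsy cohort in which a latent per-sample fibrosis level
#' drives both three fibrotic marker genes and planted sets of positively
#' coupled "fibromiRs" and negatively coupled "myomiRs" in
#' negative-binomial counts; (ii) a 2x2 FAP/MP x (control/TGFbeta1) design
#' with four planted profile archetypes; (iii) comparative-CT qPCR tables;
#' (iv) 3'UTR sequences with planted seed-match sites. All draws come from
#' a generator seeded per call; identical parameters and seed give
#' bit-identical output. The distributional laws are stand-ins chosen to
#' emulate the study's structure, not estimates of real parameters.
NULL

MARKER_GENES <- c("COL1A1", "FN1", "ACTA2")

# per-miRNA baseline abundance weights: log-normal on the log2 scale,
# normalized to sum to one so 'depth' is the expected library size
baseline_weights <- function(n_mirnas, sd = 2) {
  w <- 2^stats::rnorm(n_mirnas, 0, sd)
  w / sum(w)
}

#' Generate a synthetic biopsy cohort with latent fibrosis
#'
#' Each sample carries a latent fibrosis level `f` in `[0, 1]`: controls and
#' "low" dystrophic samples draw `f ~ U(0, 0.2)`, "high" dystrophic samples
#' `f ~ U(0.4, 1)`. A fixed fraction `prop_high` of the DMD samples
#' (`round(prop_high * n_dmd)`) is allocated to the high component, so the
#' default cohort of 8 DMD biopsies carries exactly 3 low / 5 high. Counts
#' for miRNA `i` in sample `s` are negative binomial with
#' `log2 mean = baseline_i + beta * f_s * c_i`, where `c_i` is +1 for
#' planted fibromiRs, -1 for planted myomiRs and 0 for background, and
#' variance `mu + dispersion * mu^2`. Marker-gene relative expression is
#' `exp(marker_gamma * f_s)` times log-normal noise.
#'
#' @param n_control,n_dmd numbers of control and dystrophic samples.
#' @param n_mirnas total number of miRNAs.
#' @param n_fibromirs,n_myomirs planted positively / negatively
#'   fibrosis-coupled miRNAs; their sum must not exceed `n_mirnas`.
#' @param beta effect size, log2 expression units per unit latent fibrosis.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param depth expected library size in reads.
#' @param prop_high fraction of DMD samples allocated to the high-fibrosis
#'   component.
#' @param marker_gamma slope of marker expression in latent fibrosis
#'   (natural-log scale).
#' @param marker_sd log-normal noise sd of marker expression.
#' @param seed RNG seed.
#' @return list with `counts` (integer matrix, miRNA x sample), `markers`
#'   (data frame: sample_id, COL1A1, FN1, ACTA2), `samples` (sample_id,
#'   group, latent_fibrosis, latent_class) and `mirnas` (mirna_id, class).
#' @export
simulate_cohort <- function(n_control = 3, n_dmd = 8, n_mirnas = 300,
                            n_fibromirs = 20, n_myomirs = 20,
                            beta = 2, dispersion = 0.05, depth = 1e6,
                            prop_high = 5 / 8,
                            marker_gamma = 2.35, marker_sd = 0.1,
                            seed = 1) {
  n_control <- check_count(n_control, "n_control", 1L)
  n_dmd <- check_count(n_dmd, "n_dmd", 1L)
  n_mirnas <- check_count(n_mirnas, "n_mirnas", 1L)
  n_fibromirs <- check_count(n_fibromirs, "n_fibromirs")
  n_myomirs <- check_count(n_myomirs, "n_myomirs")
  if (n_fibromirs + n_myomirs > n_mirnas) {
    stopf("n_fibromirs + n_myomirs must not exceed n_mirnas")
  }
  check_number(dispersion, "dispersion", lower = 0)
  check_number(depth, "depth", lower = 0, strict = TRUE)
  check_number(beta, "beta")
  check_number(marker_sd, "marker_sd", lower = 0)
  if (prop_high < 0 || prop_high > 1) stopf("'prop_high' must be in [0, 1]")

  withr::with_seed(seed, {
    n_high <- round(prop_high * n_dmd)
    n_low <- n_dmd - n_high
    f <- c(
      stats::runif(n_control, 0, 0.2),
      stats::runif(n_low, 0, 0.2),
      stats::runif(n_high, 0.4, 1)
    )
    samples <- data.frame(
      sample_id = c(sprintf("CT%d", seq_len(n_control)),
                    sprintf("DMD%d", seq_len(n_dmd))),
      group = c(rep("control", n_control), rep("DMD", n_dmd)),
      latent_fibrosis = f,
      latent_class = c(rep("control", n_control),
                       rep("low", n_low), rep("high", n_high)),
      stringsAsFactors = FALSE
    )

    cls <- c(rep("fibromiR", n_fibromirs), rep("myomiR", n_myomirs),
             rep("background", n_mirnas - n_fibromirs - n_myomirs))
    coupling <- c(fibromiR = 1, myomiR = -1, background = 0)[cls]
    mirnas <- data.frame(
      mirna_id = sprintf("mir-%04d", seq_len(n_mirnas)),
      class = cls,
      stringsAsFactors = FALSE
    )

    w <- baseline_weights(n_mirnas)
    n_samples <- n_control + n_dmd
    mu <- outer(w, rep(depth, n_samples)) *
      2^(outer(coupling, f) * beta)
    counts <- matrix(
      rnbinom_mu(length(mu), as.vector(mu), dispersion),
      nrow = n_mirnas,
      dimnames = list(mirnas$mirna_id, samples$sample_id)
    )

    markers <- data.frame(sample_id = samples$sample_id,
                          stringsAsFactors = FALSE)
    for (m in MARKER_GENES) {
      markers[[m]] <- exp(marker_gamma * f) *
        stats::rlnorm(n_samples, 0, marker_sd)
    }

    list(counts = counts, markers = markers, samples = samples,
         mirnas = mirnas)
  })
}

DESIGN_CONDITIONS <- c("FAP_control", "FAP_TGFB", "MP_control", "MP_TGFB")

# log2 offsets (relative to the miRNA's own baseline) per archetype:
# C1 MP-enriched, repressed by TGFb1 in MPs; C2 MP-enriched, unresponsive;
# C3 FAP-enriched, repressed by TGFb1 in FAPs; C4 FAP-enriched, induced.
archetype_offsets <- function(class, e, r) {
  switch(class,
    C1 = c(FAP_control = -e, FAP_TGFB = -e, MP_control = 0, MP_TGFB = -r),
    C2 = c(FAP_control = -e, FAP_TGFB = -e, MP_control = 0, MP_TGFB = 0),
    C3 = c(FAP_control = 0, FAP_TGFB = -r, MP_control = -e, MP_TGFB = -e),
    C4 = c(FAP_control = 0, FAP_TGFB = r, MP_control = -e, MP_TGFB = -e),
    background = c(FAP_control = 0, FAP_TGFB = 0, MP_control = 0, MP_TGFB = 0),
    stopf("unknown archetype class '%s'", class)
  )
}

#' Generate a synthetic 2x2 FAP/MP x TGFbeta1 design
#'
#' Simulates counts for the four conditions FAP-control, FAP-TGFbeta1,
#' MP-control and MP-TGFbeta1 with planted miRNA archetypes: C1 (MP-enriched,
#' repressed by TGFbeta1), C2 (MP-enriched, unresponsive), C3 (FAP-enriched,
#' repressed) and C4 (FAP-enriched, induced), plus unstructured background.
#'
#' @param n_replicates samples per condition.
#' @param archetype_counts named integer vector with entries `C1`..`C4` and
#'   `background`.
#' @param enrichment_lfc log2 cell-type enrichment of planted archetypes.
#' @param response_lfc log2 TGFbeta1 response in the enriched cell type.
#' @param dispersion NB dispersion alpha.
#' @param depth expected library size per sample.
#' @param seed RNG seed.
#' @return list with `counts` (miRNA x sample), `samples` (sample_id, cell,
#'   treatment, condition) and `mirnas` (mirna_id, class).
#' @export
simulate_design <- function(n_replicates = 3,
                            archetype_counts = c(C1 = 10, C2 = 10, C3 = 10,
                                                 C4 = 10, background = 60),
                            enrichment_lfc = 4, response_lfc = 2,
                            dispersion = 0.02, depth = 1e6, seed = 1) {
  n_replicates <- check_count(n_replicates, "n_replicates", 2L)
  need <- c("C1", "C2", "C3", "C4", "background")
  if (!all(need %in% names(archetype_counts))) {
    stopf("'archetype_counts' needs entries %s", paste(need, collapse = ", "))
  }
  archetype_counts <- archetype_counts[need]
  if (any(archetype_counts < 0)) stopf("archetype counts must be >= 0")
  n_mirnas <- sum(archetype_counts)
  if (n_mirnas < 1) stopf("at least one miRNA required")
  check_number(dispersion, "dispersion", lower = 0)
  check_number(depth, "depth", lower = 0, strict = TRUE)

  withr::with_seed(seed, {
    cls <- rep(need, times = archetype_counts)
    mirnas <- data.frame(
      mirna_id = sprintf("mir-%04d", seq_len(n_mirnas)),
      class = cls,
      stringsAsFactors = FALSE
    )
    samples <- data.frame(
      sample_id = paste0(rep(DESIGN_CONDITIONS, each = n_replicates), "_",
                         rep(seq_len(n_replicates), 4L)),
      cell = rep(c("FAP", "FAP", "MP", "MP"), each = n_replicates),
      treatment = rep(c("control", "TGFB", "control", "TGFB"),
                      each = n_replicates),
      condition = rep(DESIGN_CONDITIONS, each = n_replicates),
      stringsAsFactors = FALSE
    )

    w <- baseline_weights(n_mirnas)
    off <- t(vapply(cls, archetype_offsets, numeric(4L),
                    e = enrichment_lfc, r = response_lfc))
    colnames(off) <- DESIGN_CONDITIONS
    mu <- depth * w * 2^off[, samples$condition, drop = FALSE]
    counts <- matrix(
      rnbinom_mu(length(mu), as.vector(mu), dispersion),
      nrow = n_mirnas,
      dimnames = list(mirnas$mirna_id, samples$sample_id)
    )
    list(counts = counts, samples = samples, mirnas = mirnas)
  })
}

#' Generate a synthetic comparative-CT qPCR table
#'
#' Target-gene Ct values are built from the reference gene as
#' `Ct_target = Ct_ref + baseline_dct - true_log2_fold * [treated] + N(0, noise_sd)`,
#' so that the comparative-CT fold change of treated versus control inverts
#' to `2^true_log2_fold` in expectation (exactly, when `noise_sd = 0`).
#'
#' @param n_samples replicates per arm (control and treated).
#' @param true_log2_fold planted log2 fold change of the target.
#' @param noise_sd sd of Gaussian Ct noise (cycles).
#' @param target,reference gene labels.
#' @param baseline_dct control-arm delta-Ct (cycles).
#' @param ct_ref reference-gene Ct (cycles).
#' @param seed RNG seed.
#' @return data frame with columns sample_id, condition, target, ct_target,
#'   reference, ct_ref, replicate.
#' @export
simulate_ct_table <- function(n_samples = 3, true_log2_fold = 1,
                              noise_sd = 0.2, target = "COL1A1",
                              reference = "TBP", baseline_dct = 5,
                              ct_ref = 25, seed = 1) {
  n_samples <- check_count(n_samples, "n_samples", 1L)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(true_log2_fold, "true_log2_fold")
  condition <- rep(c("control", "treated"), each = n_samples)
  withr::with_seed(seed, {
    ct_target <- ct_ref + baseline_dct -
      true_log2_fold * (condition == "treated") +
      stats::rnorm(2L * n_samples, 0, noise_sd)
    data.frame(
      sample_id = paste0(condition, "_", rep(seq_len(n_samples), 2L)),
      condition = condition,
      target = target,
      ct_target = ct_target,
      reference = reference,
      ct_ref = ct_ref,
      replicate = rep(seq_len(n_samples), 2L),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a UTR sequence with planted seed-match sites
#'
#' Draws a background sequence uniformly over A/C/G/U, writes the exact site
#' sequence for each planted `(position, site_type)` pair, and
#' rejection-resamples background windows until the seed scan reports
#' exactly the planted sites (no accidental matches, no type upgrades from
#' flanking bases).
#'
#' @param utr_length UTR length in nt.
#' @param mirna_seq miRNA sequence (>= 8 nt).
#' @param planted data frame with columns `position` (1-based start) and
#'   `site_type` (one of 8mer, 7mer-m8, 7mer-A1, 6mer); may have zero rows.
#' @param seed RNG seed.
#' @return list with `sequence` (RNA letters) and `truth` (data frame:
#'   start, end, site_type, site_seq).
#' @export
simulate_utr_sites <- function(utr_length, mirna_seq, planted = NULL,
                               seed = 1) {
  utr_length <- check_count(utr_length, "utr_length", 6L)
  pat <- seed_patterns(mirna_seq)
  if (is.null(planted)) {
    planted <- data.frame(position = integer(), site_type = character())
  }
  if (nrow(planted) > 0) {
    if (!all(c("position", "site_type") %in% names(planted))) {
      stopf("'planted' needs columns 'position' and 'site_type'")
    }
    if (!all(planted$site_type %in% SITE_TYPES)) {
      stopf("unknown site type in 'planted'")
    }
  }
  starts <- as.integer(planted$position)
  types <- as.character(planted$site_type)
  spans <- vapply(types, site_span, integer(1))
  ends <- starts + spans - 1L
  if (any(starts < 1L) || any(ends > utr_length)) {
    stopf("planted site out of bounds")
  }
  if (nrow(planted) > 1) {
    ord <- order(starts)
    if (any(starts[ord][-1] <= ends[ord][-length(ord)])) {
      stopf("planted sites overlap")
    }
  }
  truth <- data.frame(
    start = starts, end = ends, site_type = types,
    site_seq = vapply(types, function(tp) site_sequence(pat, tp),
                      character(1)),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  planted_pos <- unlist(mapply(seq.int, truth$start, truth$end,
                               SIMPLIFY = FALSE))

  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), utr_length, replace = TRUE)
    for (i in seq_len(nrow(truth))) {
      chars[truth$start[i]:truth$end[i]] <-
        strsplit(truth$site_seq[i], "", fixed = TRUE)[[1]]
    }
    key <- function(d) paste(d$start, d$end, d$site_type)
    for (iter in seq_len(200L)) {
      found <- seed_sites(mirna_seq, paste(chars, collapse = ""))
      extra <- found[!key(found) %in% key(truth), , drop = FALSE]
      if (nrow(extra) == 0L) break
      # resample free background positions in and around offending loci
      bad <- unique(unlist(mapply(
        function(s, e) max(1L, s - 1L):min(utr_length, e + 1L),
        extra$start, extra$end, SIMPLIFY = FALSE
      )))
      bad <- setdiff(bad, planted_pos)
      if (length(bad) == 0L) {
        stopf("cannot place planted sites without spurious matches")
      }
      chars[bad] <- sample(c("A", "C", "G", "T"), length(bad),
                           replace = TRUE)
    }
    if (nrow(extra) > 0L) {
      stopf("failed to eliminate accidental seed matches")
    }
    list(sequence = chartr("T", "U", paste(chars, collapse = "")),
         truth = truth)
  })
}
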