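#' Default drug panel for synthetic screens
#'
#' Eight-drug panel with the conventional vehicle assignment: platinum
#' chemotherapy (cisplatin, gemcitabine and their combination) referenced
#' to H2O, everything else to DMSO.
#'
#' @return Data.frame with columns `drug`, `vehicle_class`.
#' @export
default_drug_panel <- function() {
  data.frame(
    drug = c("epirubicin", "mitomycin_c", "doxorubicin", "docetaxel",
             "cisplatin", "gemcitabine", "cisp_gem", "lapatinib",
             "erdafitinib"),
    vehicle_class = c("DMSO", "DMSO", "DMSO", "DMSO",
                      "H2O", "H2O", "H2O", "DMSO", "DMSO"),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic matched tumor/organoid cohort
#'
#' Parameters of the cohort generator, chosen to emulate a matched
#' PT/PDO exome-plus-drug-screen study at desk scale: a 200-gene panel on
#' five pseudo-chromosomes, a shared-SNV fraction of 0.73 between the
#' members of a pair, subclonal private mutations (CCF scaled down), exome
#' territory of 30 Mb, sequencing noise of Poisson(80) coverage with
#' binomial alt reads, and CellTiter-Glo-scale plate readouts with 7
#' vehicle and 3 treated replicates per condition.
#'
#' @param n_pairs Number of matched PT/PDO pairs.
#' @param seed Integer seed fixing every stochastic draw.
#' @param purity_range Range of per-sample tumor purity (uniform draw).
#' @param polyploid_fraction Fraction of pairs with a polyploid genome
#'   (near-universal gains; genomic burden close to 1).
#' @param shared_snv_fraction Fraction of each sample's somatic SNVs shared
#'   with its matched partner (default 0.73).
#' @param private_ccf_scale Multiplier (< 1) applied to the cancer cell
#'   fraction of private mutations, making them subclonal.
#' @param snvs_per_sample Somatic SNVs per sample before filtering.
#' @param target_mb Sequenced territory in Mb (the TMB denominator).
#' @param n_genes,n_chromosomes Gene panel layout.
#' @param drug_panel Data.frame of `drug` and `vehicle_class`.
#' @param planted_effects Data.frame with columns `gene`, `drug`, `effect`
#'   (z-score units; negative = carriers more sensitive) and
#'   `carrier_fraction`; use a 0-row data.frame for a null screen.
#' @param vehicle_mu,vehicle_cv Mean and coefficient of variation of
#'   vehicle-well luminescence readouts.
#' @param replicates_per_condition Treated replicates per drug condition.
#' @param vehicle_replicates Vehicle wells per vehicle class.
#' @param n_gene_sets Number of random gene sets in the synthetic
#'   collection (a dedicated pathway per planted gene is always added).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 8, seed = 1L,
                          purity_range = c(0.55, 0.95),
                          polyploid_fraction = 0.25,
                          shared_snv_fraction = 0.73,
                          private_ccf_scale = 0.4,
                          snvs_per_sample = 300,
                          target_mb = 30,
                          n_genes = 200, n_chromosomes = 5,
                          drug_panel = default_drug_panel(),
                          planted_effects = data.frame(
                            gene = "FGFR3", drug = "erdafitinib",
                            effect = -2, carrier_fraction = 0.4),
                          vehicle_mu = 1e4, vehicle_cv = 0.07,
                          replicates_per_condition = 3,
                          vehicle_replicates = 7,
                          n_gene_sets = 15) {
  fracs <- c(purity_range, polyploid_fraction, shared_snv_fraction,
             private_ccf_scale)
  if (any(fracs < 0 | fracs > 1))
    stop("purity_range, polyploid_fraction, shared_snv_fraction and ",
         "private_ccf_scale must lie in [0, 1]")
  if (private_ccf_scale >= 1)
    stop("private_ccf_scale must be < 1 (private mutations are subclonal)")
  stopifnot(purity_range[1] <= purity_range[2], target_mb > 0,
            snvs_per_sample >= 1, replicates_per_condition >= 2,
            vehicle_replicates >= 2)
  structure(
    list(n_pairs = as.integer(n_pairs), seed = as.integer(seed),
         purity_range = purity_range,
         polyploid_fraction = polyploid_fraction,
         shared_snv_fraction = shared_snv_fraction,
         private_ccf_scale = private_ccf_scale,
         snvs_per_sample = as.integer(snvs_per_sample),
         target_mb = target_mb, n_genes = as.integer(n_genes),
         n_chromosomes = as.integer(n_chromosomes),
         drug_panel = drug_panel, planted_effects = planted_effects,
         vehicle_mu = vehicle_mu, vehicle_cv = vehicle_cv,
         replicates_per_condition = as.integer(replicates_per_condition),
         vehicle_replicates = as.integer(vehicle_replicates),
         n_gene_sets = as.integer(n_gene_sets)),
    class = "cohort_config")
}

# recognizable bladder-cancer genes head the synthetic panel so planted
# effects and gene sets can use familiar symbols
panel_gene_names <- function(n) {
  known <- c("FGFR3", "PIK3CA", "TP53", "RB1", "CDKN2A", "ARID1A", "ERBB2",
             "TSC1", "KMT2D", "EGFR", "HRAS", "PTEN", "CCND1", "MDM2",
             "BRCA2", "ATM", "ERCC2", "KRAS", "AKT1", "BRAF")
  c(known[seq_len(min(n, length(known)))],
    sprintf("G%03d", seq_len(max(0, n - length(known)))))
}

synthetic_panel <- function(n_genes, n_chromosomes, chrom_len = 1e8) {
  per_chrom <- ceiling(n_genes / n_chromosomes)
  rows <- list()
  g <- 0L
  names_all <- panel_gene_names(n_genes)
  for (c_i in seq_len(n_chromosomes)) {
    k <- min(per_chrom, n_genes - g)
    if (k <= 0) break
    starts <- round(seq(2e6, chrom_len - 2e6, length.out = per_chrom))[seq_len(k)]
    rows[[c_i]] <- data.frame(
      gene = names_all[g + seq_len(k)], chrom = paste0("chr", c_i),
      start = starts, end = starts + 19999L, stringsAsFactors = FALSE)
    g <- g + k
  }
  gene_panel(do.call(rbind, rows))
}

# allele-specific copy-number states and their frequencies; polyploid
# genomes are dominated by gains so their genomic burden is ~1
cn_state_table <- function(polyploid) {
  if (polyploid)
    data.frame(cnA = c(2, 2, 3, 3, 4, 2, 1), cnB = c(2, 1, 2, 1, 2, 0, 1),
               p = c(.45, .25, .12, .08, .05, .03, .02))
  else
    data.frame(cnA = c(1, 2, 1, 2, 2, 3, 3), cnB = c(1, 1, 0, 0, 2, 1, 2),
               p = c(.62, .12, .10, .05, .05, .04, .02))
}

draw_segments <- function(n_chromosomes, polyploid, chrom_len = 1e8,
                          segs_per_chrom = 6) {
  st <- cn_state_table(polyploid)
  rows <- lapply(seq_len(n_chromosomes), function(c_i) {
    bp <- sort(sample(seq(5e6, chrom_len - 5e6, by = 1e5),
                      segs_per_chrom - 1))
    bounds <- c(0, bp, chrom_len)
    pick <- sample(nrow(st), segs_per_chrom, replace = TRUE, prob = st$p)
    data.frame(chrom = paste0("chr", c_i), start = bounds[-length(bounds)],
               end = bounds[-1], cnA = st$cnA[pick], cnB = st$cnB[pick],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

perturb_segments <- function(segments, polyploid, rate = 0.06) {
  st <- cn_state_table(polyploid)
  redraw <- which(runif(nrow(segments)) < rate)
  if (length(redraw) > 0) {
    pick <- sample(nrow(st), length(redraw), replace = TRUE, prob = st$p)
    segments$cnA[redraw] <- st$cnA[pick]
    segments$cnB[redraw] <- st$cnB[pick]
  }
  segments
}

# allele-specific CN state of the segment containing each 0-based position
cn_at_position <- function(segments, chrom, pos0) {
  n <- length(pos0)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("cnA", "cnB")))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sc <- segments[segments$chrom == ch, , drop = FALSE]
    sc <- sc[order(sc$start), , drop = FALSE]
    if (nrow(sc) == 0) next
    idx <- findInterval(pos0[sel], sc$start)
    ok <- idx >= 1 & pos0[sel] < sc$end[pmax(idx, 1)]
    out[sel[ok], "cnA"] <- sc$cnA[idx[ok]]
    out[sel[ok], "cnB"] <- sc$cnB[idx[ok]]
  }
  out
}

draw_loci <- function(n, panel) {
  gi <- sample(nrow(panel), n, replace = TRUE)
  pos <- panel$start[gi] +
    floor(runif(n) * (panel$end[gi] - panel$start[gi] + 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  impact <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), n,
                   replace = TRUE, prob = c(.15, .45, .20, .20))
  data.frame(chrom = panel$chrom[gi], pos = pos, ref = ref, alt = alt,
             gene = panel$gene[gi], impact = impact,
             stringsAsFactors = FALSE)
}

draw_ccf <- function(n) {
  # mostly clonal, with a subclonal minority
  ifelse(runif(n) < 0.8, 1, runif(n, 0.5, 1))
}

# observe loci with known true CCF through a sample's purity, local copy
# number and binomial sequencing noise (multiplicity 1)
observe_snvs <- function(loci, ccf, segments, purity, mean_coverage = 80) {
  cn <- cn_at_position(segments, loci$chrom, loci$pos - 1L)
  cn_t <- cn[, "cnA"] + cn[, "cnB"]
  cn_t[is.na(cn_t)] <- 2
  af_true <- purity * 1 * ccf / (purity * cn_t + (1 - purity) * 2)
  af_true[cn_t == 0] <- 0
  cov <- pmax(rpois(nrow(loci), mean_coverage), 1L)
  alt <- rbinom(nrow(loci), cov, af_true)
  data.frame(loci[c("chrom", "pos", "ref", "alt")],
             tumor_coverage = cov, tumor_alt_reads = alt,
             normal_alt_reads = 0L,
             allelic_fraction = alt / cov,
             gene = loci$gene, impact = loci$impact,
             true_ccf = ccf, stringsAsFactors = FALSE)
}

#' Generate a synthetic matched tumor/organoid cohort
#'
#' Produces a full desk-scale study: matched PT/PDO segment profiles that
#' share a per-pair backbone (with a minority of discordant segments and a
#' polyploid subset with near-universal gains), somatic SNV tables with a
#' controlled shared fraction and subclonal private mutations observed
#' through binomial sequencing noise, a gene panel, a synthetic gene-set
#' collection, drug-screen plates with planted genotype-drug effects, and a
#' `truth` record of every planted parameter for recovery testing.
#'
#' Each stage draws from a sub-seed derived from `config$seed`, so the same
#' configuration always yields the same cohort.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `profiles`
#'   (list of [segment_profile()]), `snvs` (named list of SNV data.frames,
#'   with a `true_ccf` column), `panel`, `gene_sets`, `plates`,
#'   `matched_pairs` (data.frame `pt`/`pdo`) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_pairs < 2)
    stop("n_pairs must be >= 2: pairwise analyses are undefined otherwise")
  set.seed(config$seed)
  panel <- synthetic_panel(config$n_genes, config$n_chromosomes)

  # planted effects: carriers chosen pair-wise before any per-pair draws
  pe <- config$planted_effects
  if (nrow(pe) > 0) {
    missing_genes <- setdiff(pe$gene, panel$gene)
    if (length(missing_genes) > 0)
      stop("planted effect gene(s) absent from the panel: ",
           paste(missing_genes, collapse = ", "))
    carriers <- lapply(seq_len(nrow(pe)), function(i) {
      n_carr <- max(2L, round(pe$carrier_fraction[i] * config$n_pairs))
      sort(sample(config$n_pairs, min(n_carr, config$n_pairs)))
    })
  } else carriers <- list()

  classes <- sample(tumor_class_levels(), config$n_pairs, replace = TRUE,
                    prob = c(0.3, 0.3, 0.4))
  polyploid <- runif(config$n_pairs) < config$polyploid_fraction

  profiles <- list()
  snvs <- list()
  pair_rows <- list()
  for (i in seq_len(config$n_pairs)) {
    set.seed(config$seed + 1000L * i)
    pt_id <- sprintf("P%02d_PT", i)
    pdo_id <- sprintf("P%02d_PDO", i)
    purity <- runif(2, config$purity_range[1], config$purity_range[2])
    backbone <- draw_segments(config$n_chromosomes, polyploid[i])
    pt_seg <- backbone
    pdo_seg <- perturb_segments(backbone, polyploid[i])
    prof_pt <- segment_profile(pt_id, pt_seg, "PT", classes[i], purity[1])
    prof_pdo <- segment_profile(pdo_id, pdo_seg, "PDO", classes[i], purity[2])

    n <- config$snvs_per_sample
    n_shared <- round(config$shared_snv_fraction * n)
    n_private <- n - n_shared
    loci <- draw_loci(n_shared + 2L * n_private, panel)
    # regenerate any colliding keys so (chrom,pos,ref,alt) is unique
    for (tries in 1:10) {
      dup <- duplicated(paste(loci$chrom, loci$pos, loci$ref, loci$alt))
      if (!any(dup)) break
      loci[dup, ] <- draw_loci(sum(dup), panel)
    }
    shared_idx <- seq_len(n_shared)
    priv_pt_idx <- n_shared + seq_len(n_private)
    priv_pdo_idx <- n_shared + n_private + seq_len(n_private)
    ccf <- numeric(nrow(loci))
    ccf[shared_idx] <- draw_ccf(n_shared)
    ccf[-shared_idx] <- config$private_ccf_scale * draw_ccf(2L * n_private)

    # planted feature SNVs are clonal, high-impact and shared by the pair
    planted_loci <- NULL
    for (k in seq_along(carriers)) {
      if (!i %in% carriers[[k]]) next
      g <- panel[panel$gene == pe$gene[k], ]
      lk <- data.frame(chrom = g$chrom,
                       pos = g$start + sample(200, 1),
                       ref = "C", alt = "T", gene = g$gene,
                       impact = "HIGH", stringsAsFactors = FALSE)
      planted_loci <- rbind(planted_loci, lk)
    }
    idx_pt <- c(shared_idx, priv_pt_idx)
    idx_pdo <- c(shared_idx, priv_pdo_idx)
    obs <- function(idx, seg, pur) {
      l <- loci[idx, , drop = FALSE]
      cc <- ccf[idx]
      if (!is.null(planted_loci)) {
        l <- rbind(l, planted_loci)
        cc <- c(cc, rep(1, nrow(planted_loci)))
      }
      observe_snvs(l, cc, seg, pur)
    }
    snvs[[pt_id]] <- obs(idx_pt, pt_seg, purity[1])
    snvs[[pdo_id]] <- obs(idx_pdo, pdo_seg, purity[2])
    profiles[[pt_id]] <- prof_pt
    profiles[[pdo_id]] <- prof_pdo
    pair_rows[[i]] <- data.frame(
      pair = i, pt = pt_id, pdo = pdo_id, tumor_class = classes[i],
      polyploid = polyploid[i], purity_pt = purity[1],
      purity_pdo = purity[2], n_shared_loci = n_shared,
      n_private_per_side = n_private, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)

  # drug plates are screened on the organoids
  plates <- list()
  sd_v <- config$vehicle_cv * config$vehicle_mu
  for (i in seq_len(config$n_pairs)) {
    set.seed(config$seed + 500000L + 1000L * i)
    pdo_id <- pairs$pdo[i]
    well_rows <- list()
    for (vc in unique(config$drug_panel$vehicle_class)) {
      well_rows[[vc]] <- data.frame(
        condition = vc, vehicle_class = vc,
        replicate = seq_len(config$vehicle_replicates),
        readout = pmax(rnorm(config$vehicle_replicates,
                             config$vehicle_mu, sd_v), 0),
        stringsAsFactors = FALSE)
    }
    for (d in seq_len(nrow(config$drug_panel))) {
      drug <- config$drug_panel$drug[d]
      z_true <- rnorm(1, 0, 0.25)  # sample-level response jitter
      for (k in seq_along(carriers)) {
        if (pe$drug[k] == drug && i %in% carriers[[k]])
          z_true <- z_true + pe$effect[k]
      }
      well_rows[[drug]] <- data.frame(
        condition = drug,
        vehicle_class = config$drug_panel$vehicle_class[d],
        replicate = seq_len(config$replicates_per_condition),
        readout = pmax(rnorm(config$replicates_per_condition,
                             config$vehicle_mu + z_true * sd_v, sd_v), 0),
        stringsAsFactors = FALSE)
    }
    plates[[pdo_id]] <- plate_data(pdo_id, do.call(rbind, well_rows))
  }

  # synthetic gene-set collection over the panel universe
  set.seed(config$seed + 900000L)
  sets <- list()
  for (s in seq_len(config$n_gene_sets)) {
    sets[[sprintf("SET%02d", s)]] <-
      sample(panel$gene, sample(10:25, 1))
  }
  for (k in seq_len(nrow(pe))) {
    nm <- paste0(pe$gene[k], "_PATHWAY")
    sets[[nm]] <- unique(c(pe$gene[k], sample(panel$gene, 11)))
  }
  gene_sets <- gene_set_collection(sets, background = panel$gene)

  truth <- list(
    config = config,
    pairs = pairs,
    planted_effects = if (nrow(pe) == 0) cbind(pe, carriers = character(0))
    else cbind(pe, carriers = vapply(carriers, function(cc)
      paste(pairs$pdo[cc], collapse = ","), character(1))))

  structure(list(profiles = profiles, snvs = snvs, panel = panel,
                 gene_sets = gene_sets, plates = plates,
                 matched_pairs = pairs[c("pt", "pdo")], truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$matched_pairs), "matched PT/PDO pairs,",
      length(x$panel$gene), "panel genes,",
      length(x$gene_sets$sets), "gene sets,",
      nrow(x$truth$config$drug_panel), "drugs\n")
  invisible(x)
}

#' Flat table of planted cohort parameters
#'
#' One row per planted genotype-drug effect (zero rows for a null cohort),
#' with the generator's scalar configuration attached as the `config`
#' attribute, for parameter-recovery tests against analysis output.
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @return Data.frame with columns `gene`, `drug`, `effect`,
#'   `carrier_fraction`, `carriers`.
#' @export
truth_report <- function(truth) {
  out <- as.data.frame(truth$planted_effects)
  rownames(out) <- NULL
  attr(out, "config") <- truth$config
  out
}
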