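#' Configuration for the synthetic study generator
#'
#' Defines a miniature two-group adipose RNA-seq study with planted ground
#' truth: a reference annotation (protein-coding and known-lincRNA loci), an
#' assembled transcriptome carrying planted novel intergenic noncoding
#' transcripts plus decoys that each violate exactly one lincRNA filter, a
#' NB count matrix with planted fold changes and planted lincRNA-target
#' co-expression, sample metadata mirroring a fat-vs-lean backfat design,
#' a QTL interval catalogue, and a protein homology-evidence table.
#'
#' @param seed integer RNG seed; one seed governs every draw
#' @param n_chroms,chrom_length genome shape (default 5 chromosomes of 10 Mb)
#' @param n_coding_genes protein-coding genes in the reference (default 200)
#' @param n_known_lincrnas known lincRNA genes in the reference (default 20)
#' @param n_novel_intergenic planted novel intergenic noncoding transcripts
#'   (default 30); these are the recoverable truth
#' @param n_decoy_orf intergenic decoys carrying a planted ORF >= 450 nt,
#'   eliminated by the coding-potential filter (default 10)
#' @param n_decoy_structure intergenic decoys violating the structural
#'   filter: single-exon and sub-200-bp transcripts (default 5)
#' @param n_decoy_homology intergenic noncoding decoys with planted protein
#'   homology hits below 1e-5 (default 5)
#' @param n_decoy_unexpressed intergenic noncoding decoys with all-zero
#'   counts, eliminated by the expression filter (default 3)
#' @param n_samples_per_group samples per group (default 10)
#' @param nb_dispersion NB dispersion of the count model (default 0.05)
#' @param de_gene_fraction fraction of coding genes with a planted fold
#'   change (default 0.1)
#' @param planted_log2fc absolute planted log2 fold change (default 2)
#' @param n_de_lincrnas lincRNA genes with a planted fold change (default 5)
#' @param qtl_count QTL intervals in the catalogue (default 50)
#' @param fat_qtl_fraction fraction of QTLs labelled fat_deposition and
#'   anchored on a planted lincRNA locus (default 0.4)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1, n_chroms = 5, chrom_length = 1e7,
                       n_coding_genes = 200, n_known_lincrnas = 20,
                       n_novel_intergenic = 30, n_decoy_orf = 10,
                       n_decoy_structure = 5, n_decoy_homology = 5,
                       n_decoy_unexpressed = 3, n_samples_per_group = 10,
                       nb_dispersion = 0.05, de_gene_fraction = 0.1,
                       planted_log2fc = 2, n_de_lincrnas = 5,
                       qtl_count = 50, fat_qtl_fraction = 0.4) {
  cfg <- list(seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
              n_coding_genes = n_coding_genes,
              n_known_lincrnas = n_known_lincrnas,
              n_novel_intergenic = n_novel_intergenic,
              n_decoy_orf = n_decoy_orf, n_decoy_structure = n_decoy_structure,
              n_decoy_homology = n_decoy_homology,
              n_decoy_unexpressed = n_decoy_unexpressed,
              n_samples_per_group = n_samples_per_group,
              nb_dispersion = nb_dispersion,
              de_gene_fraction = de_gene_fraction,
              planted_log2fc = planted_log2fc,
              n_de_lincrnas = n_de_lincrnas, qtl_count = qtl_count,
              fat_qtl_fraction = fat_qtl_fraction)
  counts <- unlist(cfg[grep("^n_|_count$", names(cfg))])
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (n_samples_per_group < 2) stop("need >= 2 samples per group")
  structure(cfg, class = "sim_config")
}

# sample() that never expands a length-1 x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# noncoding sequence: uniform draws, regenerated until the longest complete
# ORF is comfortably below the coding-potential boundary
# orf/300 + orf/L = 1.35 (construction check with a 0.85 safety margin)
noncoding_seq <- function(len) {
  limit <- 1.35 / (1 / 300 + 1 / len)
  thr <- min(0.85 * limit, 290)
  for (i in 1:500) {
    s <- rand_seq(len)
    if (find_longest_orf(s)$longest_orf_nt <= thr) return(s)
  }
  stop("could not construct a noncoding sequence of length ", len)
}

# sequence with a planted complete ORF of orf_nt (multiple of 3, >= 9)
coding_seq <- function(len, orf_nt) {
  stopifnot(orf_nt %% 3 == 0, orf_nt >= 9, orf_nt <= len)
  non_stop <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  bg <- rand_seq(len)
  off <- resample(0:(len - orf_nt), 1)
  orf <- paste0("ATG",
                paste(resample(non_stop, orf_nt / 3 - 2, replace = TRUE),
                      collapse = ""),
                resample(c("TAA", "TAG", "TGA"), 1))
  paste0(substr(bg, 1, off), orf, substr(bg, off + orf_nt + 1, len))
}

# exon chain anchored at `anchor` (0-based), fitting within ~22 kb
random_exons <- function(anchor, n_ex, exon_range, intron_range) {
  ex_len <- resample(seq(exon_range[1], exon_range[2]), n_ex, replace = TRUE)
  in_len <- if (n_ex > 1) {
    resample(seq(intron_range[1], intron_range[2]), n_ex - 1, replace = TRUE)
  } else integer(0)
  starts <- anchor + c(0, cumsum(ex_len[-n_ex] + in_len))
  data.frame(start = starts, end = starts + ex_len)
}

#' Generate a synthetic study with planted ground truth
#'
#' Writes the full input set of the pipeline to `outdir` (reference.gtf,
#' assembly.gtf, transcripts.fa, counts.tsv, samples.tsv, qtl.tsv,
#' homology_evidence.tsv, ground_truth.json) and returns the ground truth.
#' Identical config (including seed) gives byte-identical files.
#'
#' Loci are placed on a 30-kb grid with at most ~22 kb of span each, so
#' planted loci never overlap; novel/decoy transcripts are therefore
#' intergenic by construction. Counts are NB draws with per-gene means drawn
#' log-uniformly from 5 to 5000; planted differentially expressed genes get
#' a fat/lean group-mean ratio of `2^planted_log2fc` with random sign.
#' Each planted DE lincRNA gene shares a lognormal per-sample latent factor
#' with two nearby coding genes (one of them itself DE), planting
#' Pearson-correlated target pairs at r around 0.8.
#'
#' @param config a [sim_config()]
#' @param outdir output directory (created if needed)
#' @return invisibly, the ground-truth list (also written as JSON):
#'   `true_lincrna_ids`, `true_known_lincrna_ids`, `true_decoy_ids` (by
#'   defect stage), `true_de_genes` (gene_id, log2fc), `true_neighbor_pairs`,
#'   `true_correlated_pairs`, `true_qtl_hits`
#' @export
generate_study <- function(config = sim_config(), outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  ## ---- locus placement on a 30-kb grid ----
  slot_bp <- 30000
  slots_per_chrom <- floor(config$chrom_length / slot_bp)
  n_struct_single <- ceiling(config$n_decoy_structure / 2)
  n_struct_short <- config$n_decoy_structure - n_struct_single
  types <- c(rep("coding", config$n_coding_genes),
             rep("known_linc", config$n_known_lincrnas),
             rep("novel", config$n_novel_intergenic),
             rep("decoy_orf", config$n_decoy_orf),
             rep("decoy_single", n_struct_single),
             rep("decoy_short", n_struct_short),
             rep("decoy_homology", config$n_decoy_homology),
             rep("decoy_unexpressed", config$n_decoy_unexpressed))
  n_loci <- length(types)
  total_slots <- config$n_chroms * slots_per_chrom
  if (n_loci > total_slots) {
    stop("infeasible placement: ", n_loci, " loci but only ", total_slots,
         " slots; increase chrom_length or n_chroms")
  }
  slot <- sort(resample(seq_len(total_slots), n_loci))
  loci <- data.frame(
    type = resample(types, n_loci),   # shuffle types over ordered slots
    chrom = paste0("chr", (slot - 1) %/% slots_per_chrom + 1),
    anchor = ((slot - 1) %% slots_per_chrom) * slot_bp +
      resample(0:2000, n_loci, replace = TRUE),
    strand = resample(c("+", "-"), n_loci, replace = TRUE),
    stringsAsFactors = FALSE
  )
  idx_by_type <- split(seq_len(n_loci), loci$type)

  ## ---- transcript structures ----
  tx_plan <- list(
    coding = list(n_ex = 3:12, exon = c(100, 300), intron = c(200, 1400)),
    known_linc = list(n_ex = 2:4, exon = c(200, 700), intron = c(200, 1500)),
    novel = list(n_ex = 2:4, exon = c(150, 400), intron = c(200, 1500)),
    decoy_orf = list(n_ex = 2:3, exon = c(300, 500), intron = c(200, 1500)),
    decoy_single = list(n_ex = 1, exon = c(900, 1100), intron = c(0, 0)),
    decoy_short = list(n_ex = 2, exon = c(70, 90), intron = c(200, 400)),
    decoy_homology = list(n_ex = 2:4, exon = c(150, 400), intron = c(200, 1500)),
    decoy_unexpressed = list(n_ex = 2:4, exon = c(150, 400), intron = c(200, 1500))
  )
  counters <- c(coding = 0, known_linc = 0, novel = 0, decoy_orf = 0,
                decoy_single = 0, decoy_short = 0, decoy_homology = 0,
                decoy_unexpressed = 0)
  prefix <- c(coding = "c", known_linc = "k", novel = "n", decoy_orf = "do",
              decoy_single = "ds", decoy_short = "dt", decoy_homology = "dh",
              decoy_unexpressed = "du")
  exon_rows <- vector("list", n_loci)
  loci$asm_tx <- loci$asm_gene <- loci$ref_tx <- loci$ref_gene <- NA_character_
  for (i in seq_len(n_loci)) {
    ty <- loci$type[i]
    counters[ty] <- counters[ty] + 1
    k <- counters[ty]
    plan <- tx_plan[[ty]]
    n_ex <- resample(plan$n_ex, 1)
    ex <- random_exons(loci$anchor[i], n_ex, plan$exon, plan$intron)
    loci$asm_gene[i] <- sprintf("MSTRG.%s%03d", prefix[ty], k)
    loci$asm_tx[i] <- paste0(loci$asm_gene[i], ".1")
    if (ty == "coding") {
      loci$ref_gene[i] <- sprintf("ENSSSCG%08d", k)
      loci$ref_tx[i] <- sprintf("ENSSSCT%08d", k)
    } else if (ty == "known_linc") {
      loci$ref_gene[i] <- sprintf("ALDB_G%05d", k)
      loci$ref_tx[i] <- sprintf("ALDB_T%05d", k)
    }
    exon_rows[[i]] <- cbind(ex, chrom = loci$chrom[i], strand = loci$strand[i],
                            locus = i, stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_rows)

  ref_idx <- which(loci$type %in% c("coding", "known_linc"))
  ref_exons <- exons[exons$locus %in% ref_idx, , drop = FALSE]
  ref_exons$transcript_id <- loci$ref_tx[ref_exons$locus]
  ref_exons$gene_id <- loci$ref_gene[ref_exons$locus]
  ref_biotype <- stats::setNames(
    ifelse(loci$type[ref_idx] == "coding", "protein_coding", "known_lincrna"),
    loci$ref_tx[ref_idx])
  reference <- transcript_set(
    ref_exons[, c("transcript_id", "gene_id", "chrom", "start", "end", "strand")],
    biotype = ref_biotype)

  asm_exons <- exons
  asm_exons$transcript_id <- loci$asm_tx[asm_exons$locus]
  asm_exons$gene_id <- loci$asm_gene[asm_exons$locus]
  assembly <- transcript_set(
    asm_exons[, c("transcript_id", "gene_id", "chrom", "start", "end", "strand")],
    biotype = "unassigned")

  ## ---- transcript sequences ----
  tx_len <- stats::setNames(assembly$transcripts$length,
                            assembly$transcripts$transcript_id)
  seqs <- character(n_loci)
  names(seqs) <- loci$asm_tx
  for (i in seq_len(n_loci)) {
    L <- tx_len[[loci$asm_tx[i]]]
    seqs[i] <- if (loci$type[i] == "coding") {
      coding_seq(L, 3 * floor(pmin(0.9 * L, pmax(450, 0.6 * L)) / 3))
    } else if (loci$type[i] == "decoy_orf") {
      coding_seq(L, 3 * floor(pmin(0.9 * L, pmax(450, 0.5 * L)) / 3))
    } else {
      noncoding_seq(L)
    }
  }

  ## ---- planted differential expression & correlated target pairs ----
  genes <- data.frame(gene_id = loci$asm_gene, type = loci$type,
                      chrom = loci$chrom, stringsAsFactors = FALSE)
  # coding genes are drawn more highly expressed than lincRNA-like loci,
  # emulating the lower expression of lincRNAs relative to coding genes
  genes$base_mean <- ifelse(
    genes$type == "coding",
    exp(stats::runif(n_loci, log(20), log(5000))),
    exp(stats::runif(n_loci, log(5), log(500))))
  genes$base_mean[genes$type == "decoy_unexpressed"] <- 0
  genes$log2fc <- 0
  genes$pairgroup <- NA_integer_

  n_de_coding <- floor(config$de_gene_fraction * config$n_coding_genes)
  linc_gene_idx <- c(idx_by_type$novel, idx_by_type$known_linc)
  de_linc_idx <- resample(linc_gene_idx,
                          min(config$n_de_lincrnas, length(linc_gene_idx)))
  # each DE lincRNA shares a latent factor with two nearby coding genes
  corr_pairs <- NULL
  used_coding <- integer(0)
  gl <- gene_loci(assembly)
  gl <- gl[match(loci$asm_gene, gl$gene_id), ]
  for (gidx in seq_along(de_linc_idx)) {
    li <- de_linc_idx[gidx]
    cand <- setdiff(idx_by_type$coding, used_coding)
    same_chr <- cand[loci$chrom[cand] == loci$chrom[li]]
    gap <- pmax(0, pmax(gl$start[same_chr], gl$start[li]) -
                   pmin(gl$end[same_chr], gl$end[li]))
    near <- same_chr[order(gap)]
    chosen <- utils::head(c(near, setdiff(cand, near)), 2)
    used_coding <- c(used_coding, chosen)
    genes$pairgroup[c(li, chosen)] <- gidx
    corr_pairs <- rbind(corr_pairs, data.frame(
      lincrna_gene = loci$asm_gene[li], coding_gene = loci$asm_gene[chosen],
      stringsAsFactors = FALSE))
  }
  sgn_linc <- resample(c(-1, 1), length(de_linc_idx), replace = TRUE)
  genes$log2fc[de_linc_idx] <- sgn_linc * config$planted_log2fc
  # partners of a DE lincRNA are co-regulated: DE in the same direction,
  # so the shared group effect and the latent factor align and the pair
  # correlation lands around 0.8-0.9 on FPKM
  de_partner_idx <- integer(0)
  for (gidx in seq_along(de_linc_idx)) {
    partners <- which(genes$pairgroup == gidx & genes$type == "coding")
    if (length(partners) > 0) {
      genes$log2fc[partners] <- sgn_linc[gidx] * config$planted_log2fc
      de_partner_idx <- c(de_partner_idx, partners)
    }
  }
  # pair members sit in the moderately-expressed regime so that their
  # correlation is not drowned by counting noise
  pair_members <- which(!is.na(genes$pairgroup))
  genes$base_mean[pair_members] <-
    exp(stats::runif(length(pair_members), log(50), log(500)))
  free_coding <- setdiff(idx_by_type$coding, de_partner_idx)
  extra_de <- resample(free_coding,
                       max(0, min(n_de_coding - length(de_partner_idx),
                                  length(free_coding))))
  genes$log2fc[extra_de] <- resample(c(-1, 1), length(extra_de),
                                     replace = TRUE) * config$planted_log2fc

  ## ---- counts ----
  nps <- config$n_samples_per_group
  sample_ids <- c(paste0("fat_", seq_len(nps)), paste0("lean_", seq_len(nps)))
  group <- rep(c("fat", "lean"), each = nps)
  n_samp <- 2 * nps
  tau <- 0.47   # lognormal latent-factor scale -> pair correlation ~ 0.8
  n_pairgroups <- length(de_linc_idx)
  latent <- if (n_pairgroups > 0) {
    matrix(exp(tau * stats::rnorm(n_pairgroups * n_samp) - tau^2 / 2),
           nrow = n_pairgroups)
  } else matrix(0, 0, n_samp)
  counts <- matrix(0L, nrow = n_loci, ncol = n_samp,
                   dimnames = list(genes$gene_id, sample_ids))
  for (i in seq_len(n_loci)) {
    if (genes$base_mean[i] == 0) next
    mu <- rep(genes$base_mean[i], n_samp)
    mu[group == "fat"] <- mu[group == "fat"] * 2^genes$log2fc[i]
    if (!is.na(genes$pairgroup[i])) mu <- mu * latent[genes$pairgroup[i], ]
    counts[i, ] <- stats::rnbinom(n_samp, mu = mu,
                                  size = 1 / config$nb_dispersion)
  }

  samples <- data.frame(
    sample_id = sample_ids, group = group,
    ebv = round(c(stats::runif(nps, 3, 8), stats::runif(nps, -11, -6)), 2),
    stringsAsFactors = FALSE)

  ## ---- QTL catalogue ----
  n_fat_qtl <- round(config$fat_qtl_fraction * config$qtl_count)
  fat_traits <- c("backfat_weight", "average_backfat_thickness",
                  "shoulder_subcutaneous_fat_thickness",
                  "backfat_at_last_lumbar")
  other_traits <- c("average_daily_gain", "feed_intake", "meat_ph",
                    "loin_muscle_area")
  qtl_rows <- vector("list", config$qtl_count)
  for (q in seq_len(config$qtl_count)) {
    if (q <= n_fat_qtl && length(linc_gene_idx) > 0) {
      li <- resample(linc_gene_idx, 1)
      s <- max(0, gl$start[li] - resample(200000:1000000, 1))
      e <- min(config$chrom_length, gl$end[li] + resample(200000:1000000, 1))
      qtl_rows[[q]] <- data.frame(qtl_id = sprintf("QTL%03d", q),
                                  chrom = loci$chrom[li], start = s, end = e,
                                  trait_name = resample(fat_traits, 1),
                                  trait_category = "fat_deposition",
                                  stringsAsFactors = FALSE)
    } else {
      chr <- paste0("chr", resample(seq_len(config$n_chroms), 1))
      len <- resample(500000:2000000, 1)
      s <- resample(0:(config$chrom_length - len), 1)
      qtl_rows[[q]] <- data.frame(qtl_id = sprintf("QTL%03d", q),
                                  chrom = chr, start = s, end = s + len,
                                  trait_name = resample(other_traits, 1),
                                  trait_category = "other",
                                  stringsAsFactors = FALSE)
    }
  }
  qtls <- do.call(rbind, qtl_rows)

  ## ---- homology evidence ----
  ev <- NULL
  hom_idx <- c(idx_by_type$decoy_homology, idx_by_type$decoy_orf)
  for (i in hom_idx) {
    nrow_ev <- resample(1:2, 1)
    ev <- rbind(ev, data.frame(
      transcript_id = loci$asm_tx[i],
      source = resample(c("pfam", "nr", "uniref90"), nrow_ev, replace = TRUE),
      evalue = 10^stats::runif(nrow_ev, -30, -6), stringsAsFactors = FALSE))
  }
  weak_idx <- utils::head(idx_by_type$novel, 5)   # retained: hits above cutoff
  for (i in weak_idx) {
    ev <- rbind(ev, data.frame(
      transcript_id = loci$asm_tx[i],
      source = resample(c("pfam", "nr", "uniref90"), 1),
      evalue = 10^stats::runif(1, -4, -1), stringsAsFactors = FALSE))
  }
  if (is.null(ev)) {
    ev <- data.frame(transcript_id = character(), source = character(),
                     evalue = numeric(), stringsAsFactors = FALSE)
  }

  ## ---- ground truth (brute-force recomputations, no interval index) ----
  linc_loci_idx <- linc_gene_idx
  nb <- NULL
  for (li in linc_loci_idx) {
    for (ci in idx_by_type$coding) {
      if (loci$chrom[li] != loci$chrom[ci]) next
      gap <- max(0, max(gl$start[li], gl$start[ci]) -
                   min(gl$end[li], gl$end[ci]))
      if (gap < 100000) {
        nb <- rbind(nb, data.frame(lincrna_gene = loci$asm_gene[li],
                                   coding_gene = loci$asm_gene[ci],
                                   gap = gap, stringsAsFactors = FALSE))
      }
    }
  }
  qh <- NULL
  for (li in linc_loci_idx) {
    for (q in seq_len(nrow(qtls))) {
      if (loci$chrom[li] != qtls$chrom[q]) next
      ov <- min(gl$end[li], qtls$end[q]) - max(gl$start[li], qtls$start[q])
      if (ov > 0) {
        qh <- rbind(qh, data.frame(lincrna_gene = loci$asm_gene[li],
                                   qtl_id = qtls$qtl_id[q],
                                   stringsAsFactors = FALSE))
      }
    }
  }
  truth <- list(
    true_lincrna_ids = loci$asm_tx[idx_by_type$novel],
    true_known_lincrna_ids = loci$asm_tx[idx_by_type$known_linc],
    true_decoy_ids = list(
      coding_potential = loci$asm_tx[idx_by_type$decoy_orf],
      structure = loci$asm_tx[c(idx_by_type$decoy_single,
                                idx_by_type$decoy_short)],
      homology = loci$asm_tx[idx_by_type$decoy_homology],
      expression = loci$asm_tx[idx_by_type$decoy_unexpressed]),
    true_de_genes = genes[genes$log2fc != 0, c("gene_id", "log2fc", "type")],
    true_neighbor_pairs = nb,
    true_correlated_pairs = corr_pairs,
    true_qtl_hits = qh
  )

  ## ---- write everything ----
  write_gtf(reference, file.path(outdir, "reference.gtf"), source = "ensembl_sim")
  write_gtf(assembly, file.path(outdir, "assembly.gtf"), source = "stringtie_sim")
  write_fasta(seqs, file.path(outdir, "transcripts.fa"))
  write_counts(counts, file.path(outdir, "counts.tsv"))
  write_samples(samples, file.path(outdir, "samples.tsv"))
  write_qtl_bed(qtls, file.path(outdir, "qtl.tsv"))
  utils::write.table(ev, file.path(outdir, "homology_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       dataframe = "columns", pretty = TRUE, digits = NA)
  invisible(truth)
}

#' Generate a calibration count matrix with planted fold changes
#'
#' A mixed matrix for benchmarking the differential-expression engine:
#' `de_fraction` of the genes carry a planted group fold change of
#' `2^(+/- log2fc)` at NB mean `de_mean`; the remaining null genes share
#' identical group means drawn log-uniformly from 5 to 5000. Dispersion and
#' group sizes come from `config`.
#'
#' @param n_genes total number of genes (default 2000)
#' @param config a [sim_config()]; uses `seed`, `n_samples_per_group`,
#'   `nb_dispersion`, `planted_log2fc`
#' @param de_fraction fraction of genes with a planted fold change
#'   (default `config$de_gene_fraction`)
#' @param de_mean NB mean of the planted genes in the lean group
#'   (default 500)
#' @return list with `counts` (matrix), `de_gene_ids`, and `log2fc`
#'   (named signed planted log2 fold changes)
#' @export
generate_calibration_counts <- function(n_genes = 2000, config = sim_config(),
                                        de_fraction = config$de_gene_fraction,
                                        de_mean = 500) {
  stopifnot(inherits(config, "sim_config"), n_genes >= 10,
            de_fraction > 0, de_fraction < 1)
  set.seed(config$seed)
  nps <- config$n_samples_per_group
  n_samp <- 2 * nps
  group <- rep(c("fat", "lean"), each = nps)
  n_de <- round(de_fraction * n_genes)
  n_null <- n_genes - n_de
  size <- 1 / config$nb_dispersion

  mu_null <- exp(stats::runif(n_null, log(5), log(5000)))
  null_counts <- t(vapply(mu_null, function(m_i) {
    as.integer(stats::rnbinom(n_samp, mu = m_i, size = size))
  }, integer(n_samp)))
  sgn <- resample(c(-1, 1), n_de, replace = TRUE)
  de_counts <- t(vapply(sgn, function(s) {
    mu <- rep(de_mean, n_samp)
    mu[group == "fat"] <- de_mean * 2^(s * config$planted_log2fc)
    as.integer(stats::rnbinom(n_samp, mu = mu, size = size))
  }, integer(n_samp)))

  counts <- rbind(null_counts, de_counts)
  dimnames(counts) <- list(paste0("gene_", seq_len(n_genes)),
                           c(paste0("fat_", seq_len(nps)),
                             paste0("lean_", seq_len(nps))))
  de_ids <- rownames(counts)[(n_null + 1):n_genes]
  list(counts = counts, de_gene_ids = de_ids,
       log2fc = stats::setNames(sgn * config$planted_log2fc, de_ids))
}

#' Generate a null count matrix (no planted differential expression)
#'
#' Both groups share identical NB means; a small fraction of genes (2%) are
#' all-zero so that the testing engine's exclusion path is exercised.
#'
#' @param n_genes number of genes
#' @param config a [sim_config()]; uses `seed`, `n_samples_per_group`,
#'   `nb_dispersion`
#' @return integer count matrix `n_genes` x `2 * n_samples_per_group`
#' @export
generate_null_counts <- function(n_genes, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), n_genes >= 1)
  set.seed(config$seed)
  nps <- config$n_samples_per_group
  mu <- exp(stats::runif(n_genes, log(5), log(5000)))
  mu[resample(seq_len(n_genes), ceiling(0.02 * n_genes))] <- 0
  m <- t(vapply(mu, function(m_i) {
    if (m_i == 0) rep(0L, 2 * nps) else
      as.integer(stats::rnbinom(2 * nps, mu = m_i,
                                size = 1 / config$nb_dispersion))
  }, integer(2 * nps)))
  dimnames(m) <- list(paste0("gene_", seq_len(n_genes)),
                      c(paste0("fat_", seq_len(nps)),
                        paste0("lean_", seq_len(nps))))
  m
}
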