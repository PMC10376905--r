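# Seeded generator of synthetic myeloid-panel cohorts. The marginal counts
# (variant types, class imbalance, 24-gene panel) mirror the clinical cohort
# the pipeline was designed around; the class-conditional distributions are
# a documented, fixed-form invention: MAF presence/value is the dominant
# signal, VAF straddles the 5% review threshold, coverage floors near the
# 300x QC bound, and pathogenic substitutions skew to higher Grantham
# distances. See the methods vignette for what this emulates and what it
# does not.

MYELOID_PANEL <- c("ASXL1", "CALR", "CBL", "CEBPA", "CXCR4", "DNMT3A",
                   "EZH2", "FLT3", "GATA2", "IDH1", "IDH2", "JAK2", "KIT",
                   "KRAS", "MPL", "NPM1", "NRAS", "PTEN", "RUNX1", "SF3B1",
                   "SRSF2", "TET2", "TP53", "WT1")

# dummy chromosome assignment and position window per panel gene; positions
# are opaque features to the model, no real transcript coordinates claimed
PANEL_CHROM <- c("20", "19", "11", "19", "2", "2", "7", "13", "3", "2",
                 "15", "9", "4", "12", "1", "5", "1", "10", "21", "2",
                 "17", "4", "17", "11")

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the marginal structure of a clinical myeloid-panel
#' cohort: 13,221 SNV / 73 MNV / 2,683 INDEL records, 14,957 benign vs 1,020
#' pathogenic labels, over a 24-gene panel. The per-class distribution
#' parameters control how separable the classes are; the defaults make the
#' MAF sentinel the dominant cue.
#'
#' @param n_snv,n_mnv,n_indel per-type record counts; their sum must equal
#'   `n_benign + n_pathogenic`.
#' @param n_benign,n_pathogenic per-class label counts.
#' @param genes gene panel (non-empty character vector).
#' @param maf_present_benign,maf_present_pathogenic probability that a
#'   population minor-allele frequency exists for the class.
#' @param label_noise probability that an emitted label is flipped relative
#'   to the generating class (keeps the feature-to-label map probabilistic).
#' @param seed RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_snv = 13221, n_mnv = 73, n_indel = 2683,
                          n_benign = 14957, n_pathogenic = 1020,
                          genes = MYELOID_PANEL,
                          maf_present_benign = 0.97,
                          maf_present_pathogenic = 0.4,
                          label_noise = 0.005,
                          seed = 1) {
  counts <- c(n_snv, n_mnv, n_indel, n_benign, n_pathogenic)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cohort counts must be non-negative integers", call. = FALSE)
  }
  if (n_snv + n_mnv + n_indel != n_benign + n_pathogenic) {
    stop(sprintf(
      "infeasible config: type counts sum to %d but class counts sum to %d",
      n_snv + n_mnv + n_indel, n_benign + n_pathogenic), call. = FALSE)
  }
  if (length(genes) == 0L) {
    stop("gene panel must be non-empty", call. = FALSE)
  }
  probs <- c(maf_present_benign, maf_present_pathogenic, label_noise)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  structure(list(n_snv = n_snv, n_mnv = n_mnv, n_indel = n_indel,
                 n_benign = n_benign, n_pathogenic = n_pathogenic,
                 genes = genes,
                 maf_present_benign = maf_present_benign,
                 maf_present_pathogenic = maf_present_pathogenic,
                 label_noise = label_noise, seed = seed),
            class = "cohort_config")
}

# Largest-remainder allocation of the pathogenic count across variant types,
# respecting per-type totals. INDELs are enriched (frameshifts drive
# pathogenicity), MNVs slightly.
allocate_pathogenic <- function(cfg) {
  n_type <- c(SNV = cfg$n_snv, MNV = cfg$n_mnv, INDEL = cfg$n_indel)
  w <- c(SNV = 1, MNV = 1.5, INDEL = 3.5)
  raw <- w * n_type
  if (sum(raw) == 0) {
    return(c(SNV = 0L, MNV = 0L, INDEL = 0L))
  }
  target <- cfg$n_pathogenic * raw / sum(raw)
  alloc <- pmin(floor(target), n_type)
  left <- cfg$n_pathogenic - sum(alloc)
  # hand out the remainder by largest fractional part, never exceeding the
  # per-type total
  frac <- order(target - floor(target), decreasing = TRUE)
  for (i in frac) {
    if (left == 0L) break
    room <- n_type[i] - alloc[i]
    add <- min(room, left)
    alloc[i] <- alloc[i] + add
    left <- left - add
  }
  if (left > 0L) {
    stop("infeasible config: pathogenic count exceeds total records",
         call. = FALSE)
  }
  storage.mode(alloc) <- "integer"
  alloc
}

sample_effect <- function(n, type, pathogenic) {
  if (n == 0L) return(character())
  if (type == "INDEL") {
    probs <- if (pathogenic) c(frameshift = 0.85, unknown = 0.15)
             else c(frameshift = 0.08, unknown = 0.92)
  } else {
    probs <- if (pathogenic) {
      c(missense = 0.68, nonsense = 0.25, synonymous = 0.02, unknown = 0.05)
    } else {
      c(missense = 0.18, nonsense = 0.005, synonymous = 0.445,
        unknown = 0.37)
    }
  }
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# residue pair for a missense change; pathogenic substitutions skew to high
# Grantham distance, benign ones to conservative exchanges
sample_missense_pair <- function(pathogenic) {
  ref <- sample(AA_THREE, 1L)
  others <- setdiff(rownames(GRANTHAM_MATRIX), ref)
  g <- GRANTHAM_MATRIX[ref, others]
  w <- if (pathogenic) (5 + g)^2.5 else 1 / (10 + g)^1.5
  mut <- sample(others, 1L, prob = w)
  c(ref, mut)
}

protein_and_coding <- function(effect, type, pathogenic, site) {
  ref <- sample(AA_THREE, 1L)
  switch(effect,
    synonymous = list(protein = sprintf("p.%s%d=", ref, site),
                      coding = sprintf("c.%dG>A", site * 3L), exonic = TRUE),
    missense = {
      pair <- sample_missense_pair(pathogenic)
      list(protein = sprintf("p.%s%d%s", pair[1], site, pair[2]),
           coding = sprintf("c.%dA>C", site * 3L), exonic = TRUE)
    },
    nonsense = list(protein = sprintf("p.%s%dTer", ref, site),
                    coding = sprintf("c.%dC>A", site * 3L), exonic = TRUE),
    frameshift = list(protein = sprintf("p.%s%dfs", ref, site),
                      coding = sprintf("c.%ddel", site * 3L), exonic = TRUE),
    unknown = {
      if (type == "INDEL" && stats::runif(1) < 0.4) {
        # in-frame deletion with an unknown functional consequence
        list(protein = sprintf("p.%s%ddel", ref, site),
             coding = sprintf("c.%d_%ddel", site * 3L, site * 3L + 2L),
             exonic = TRUE)
      } else {
        list(protein = "p.?",
             coding = sprintf("c.%d-12%s>%s", site * 3L, "C", "T"),
             exonic = FALSE)
      }
    },
    stop(sprintf("unhandled effect '%s'", effect), call. = FALSE))
}

# Allele-fraction mixture shared by both classes: heterozygous-like mass
# near 0.5, homozygous-like mass near 1, and a low-fraction component
# straddling the 5% review threshold. Pathogenicity in this generator is
# carried by the population-frequency and consequence features, not by VAF.
sample_vaf <- function(pathogenic) {
  u <- stats::runif(1)
  if (u < 0.50) {
    min(0.7, max(0.3, stats::rnorm(1, 0.5, 0.05)))       # het-like clone
  } else if (u < 0.75) {
    min(1, max(0.85, 1 - abs(stats::rnorm(1, 0, 0.03)))) # hom-like
  } else {
    stats::runif(1, 0.02, 0.35)                          # subclonal / noise
  }
}

sample_maf <- function(pathogenic, present_prob) {
  if (stats::runif(1) >= present_prob) {
    return(NA_real_)
  }
  if (pathogenic) {
    min(0.5, stats::rbeta(1, 1.3, 60))   # rare when present
  } else {
    min(0.5, stats::rbeta(1, 1.6, 10))   # polymorphism frequencies, with a
  }                                      # lower tail brushing the rare range
}

# negative-binomial-like depth floored near the 300x QC bound; depth is
# reported at amplicon-level granularity (multiples of 50), matching the
# coarse per-amplicon depth profile of a targeted panel
sample_coverage <- function() {
  if (stats::runif(1) < 0.03) {
    50L * sample.int(5L, 1L)                         # below the QC floor
  } else {
    300L + 50L * stats::rnbinom(1, size = 4, mu = 24)
  }
}

generate_record <- function(type, label_class, cfg) {
  gi <- sample.int(length(cfg$genes), 1L)
  # label noise: a noise fraction of rows draw their features from the
  # opposite class's distributions, so the emitted label counts stay exact
  # while the feature-to-label map remains probabilistic
  pathogenic <- if (stats::runif(1) < cfg$label_noise) !label_class else
    label_class
  effect <- sample_effect(1L, type, pathogenic)
  site <- sample.int(800L, 1L)
  pc <- protein_and_coding(effect, type, pathogenic, site)
  exon <- if (pc$exonic) sample.int(20L, 1L) else 0L
  chrom <- if (gi <= length(PANEL_CHROM)) PANEL_CHROM[gi] else
    as.character(1L + (gi %% 22L))
  present_prob <- if (pathogenic) cfg$maf_present_pathogenic else
    cfg$maf_present_benign
  label <- as.numeric(label_class)
  list(chrom = chrom,
       # amplicon panels call the same recurrent sites over and over;
       # positions are drawn from a fixed per-gene lattice of hotspots
       pos = gi * 1e6 + 500L * sample.int(6L, 1L),
       gene = cfg$genes[gi],
       variant_type = type,
       exon = exon,
       coding = pc$coding,
       protein = pc$protein,
       vaf = round(sample_vaf(pathogenic), 2),
       maf = {
         m <- sample_maf(pathogenic, present_prob)
         if (is.na(m)) NA_real_ else round(m, 6)
       },
       coverage = sample_coverage(),
       effect = effect,
       label = label)
}

#' Generate a synthetic labeled cohort
#'
#' Emits exactly the configured number of records per variant type and per
#' class, deterministic under the configured seed. Protein consequences are
#' HGVS-style strings that round-trip through the codec.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame of variant records with a `label` column.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  total <- cfg$n_snv + cfg$n_mnv + cfg$n_indel
  if (total == 0L) {
    return(empty_records())
  }
  path_by_type <- allocate_pathogenic(cfg)
  n_type <- c(SNV = cfg$n_snv, MNV = cfg$n_mnv, INDEL = cfg$n_indel)
  rows <- vector("list", total)
  k <- 0L
  for (type in names(n_type)) {
    n_path <- path_by_type[[type]]
    classes <- c(rep(TRUE, n_path), rep(FALSE, n_type[[type]] - n_path))
    for (label_class in classes) {
      k <- k + 1L
      rows[[k]] <- generate_record(type, label_class, cfg)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a small unlabeled batch for prediction smoke tests
#'
#' Emulates a single sequencing run's worth of called variants (default 89),
#' with the same generative model as [generate_cohort()] but without labels.
#'
#' @param n_variants number of records.
#' @param seed RNG seed.
#' @param pathogenic_fraction fraction of records drawn from the pathogenic
#'   generative class.
#' @return data.frame of unlabeled variant records.
#' @export
generate_toy_run <- function(n_variants = 89, seed = 1,
                             pathogenic_fraction = 0.15) {
  stopifnot(n_variants >= 1, pathogenic_fraction >= 0,
            pathogenic_fraction <= 1)
  n_path <- round(n_variants * pathogenic_fraction)
  n_ben <- n_variants - n_path
  n_indel <- round(0.17 * n_variants)
  n_snv <- n_variants - n_indel
  cfg <- cohort_config(n_snv = n_snv, n_mnv = 0, n_indel = n_indel,
                       n_benign = n_ben, n_pathogenic = n_path,
                       label_noise = 0, seed = seed)
  out <- generate_cohort(cfg)
  out$label <- NULL
  out
}

#' Write variant records to a TSV file
#'
#' UTF-8, tab-separated, header row; absent MAF values are written as empty
#' cells. Round-trips losslessly through [load_annotation_table()].
#'
#' @param records data.frame of variant records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(records, path) {
  cols <- intersect(c(RECORD_COLUMNS, "label"), names(records))
  if (nrow(records) == 0L) {
    cols <- c(RECORD_COLUMNS, "label")
    records <- empty_records()
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(records[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
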