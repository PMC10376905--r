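# Variant codec: reads annotated variant tables and turns each record into
# the 14 numeric predictors the classifier consumes.

FEATURE_NAMES <- c("chr", "POS", "TypeBin", "Exon", "Freq", "MAFbin",
                   "Coverage", "Protbin", "aarefbin", "aamutbin",
                   "aarefChemical", "aamutChemicalVal", "Grantham",
                   "varEffectBin")

RECORD_COLUMNS <- c("chrom", "pos", "gene", "variant_type", "exon", "coding",
                    "protein", "vaf", "maf", "coverage", "effect")

#' Reader options for annotation tables
#'
#' @param vaf_unit `"fraction"` (values already in \[0,1\]) or `"percent"`
#'   (divided by 100 on read).
#' @param binarize_coverage `NA` to pass raw read depth through (the
#'   default), or a numeric threshold t so that coverage is recoded
#'   0 (< t) / 1 (>= t).
#' @param column_map optional named character vector mapping canonical record
#'   fields to the column names found in the file, e.g.
#'   `c(chrom = "Chrom", vaf = "Frequency")`.
#' @return a codec dialect object.
#' @export
codec_dialect <- function(vaf_unit = c("fraction", "percent"),
                          binarize_coverage = NA,
                          column_map = NULL) {
  vaf_unit <- match.arg(vaf_unit)
  if (!is.na(binarize_coverage) &&
      (!is.numeric(binarize_coverage) || binarize_coverage <= 0)) {
    stop("binarize_coverage must be NA or a positive threshold", call. = FALSE)
  }
  structure(list(vaf_unit = vaf_unit,
                 binarize_coverage = binarize_coverage,
                 column_map = column_map),
            class = "codec_dialect")
}

#' Read a tab-separated variant annotation table
#'
#' Expects a UTF-8 TSV with a header row carrying (possibly via
#' `dialect$column_map`) the columns `chrom, pos, gene, variant_type, exon,
#' coding, protein, vaf, maf, coverage, effect` and optionally `label`.
#' Empty `maf` cells become `NA` (no population frequency known). Rows whose
#' numeric fields fail coercion are dropped with a warning naming their line
#' numbers.
#'
#' @param path file path.
#' @param dialect a [codec_dialect()].
#' @return a data.frame of variant records (zero rows for an empty file).
#' @export
load_annotation_table <- function(path, dialect = codec_dialect()) {
  if (!file.exists(path)) {
    stop(sprintf("annotation table not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(dialect$column_map)) {
    for (canon in names(dialect$column_map)) {
      src <- dialect$column_map[[canon]]
      if (src %in% names(raw)) {
        names(raw)[names(raw) == src] <- canon
      }
    }
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("annotation table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("annotation table has a header but no data rows", call. = FALSE)
    return(empty_records())
  }
  suppress_nawarn <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    chrom = as.character(raw$chrom),
    pos = suppress_nawarn(raw$pos),
    gene = as.character(raw$gene),
    variant_type = toupper(as.character(raw$variant_type)),
    exon = suppress_nawarn(raw$exon),
    coding = as.character(raw$coding),
    protein = as.character(raw$protein),
    vaf = suppress_nawarn(raw$vaf),
    maf = suppress_nawarn(raw$maf),
    coverage = suppress_nawarn(raw$coverage),
    effect = tolower(as.character(raw$effect)),
    stringsAsFactors = FALSE
  )
  if ("label" %in% names(raw)) {
    rec$label <- suppress_nawarn(raw$label)
  }
  if (dialect$vaf_unit == "percent") {
    rec$vaf <- rec$vaf / 100
  }
  # maf may legitimately be NA; every other numeric field must have coerced.
  bad <- which(is.na(rec$pos) | is.na(rec$exon) | is.na(rec$vaf) |
                 is.na(rec$coverage) |
                 (!is.na(raw$maf) & is.na(rec$maf)))
  if (length(bad) > 0L) {
    warning(sprintf("dropped %d row(s) failing numeric coercion (file line(s) %s)",
                    length(bad), paste(bad + 1L, collapse = ", ")),
            call. = FALSE)
    rec <- rec[-bad, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

empty_records <- function() {
  out <- data.frame(chrom = character(), pos = numeric(), gene = character(),
                    variant_type = character(), exon = numeric(),
                    coding = character(), protein = character(),
                    vaf = numeric(), maf = numeric(), coverage = numeric(),
                    effect = character(), label = numeric(),
                    stringsAsFactors = FALSE)
  out
}

#' Parse an HGVS protein-consequence string
#'
#' Classifies the protein-level consequence and extracts the reference and
#' mutant residue tokens. `prot_class` is 0 for intronic/splice-site
#' (`p.?`), 1 for synonymous (`p.(=)` or `p.Xxx123=`), and 2 for an
#' amino-acid change (substitution, stop gain, frameshift, deletion,
#' duplication, delins). For classes 0 and 1 both tokens are `"NA"`.
#'
#' @param protein HGVS p. string, e.g. `"p.Lys385Thr"`, `"p.Ser1518Ter"`,
#'   `"p.Leu422="`, `"p.?"`.
#' @return list with `ref`, `mut`, `prot_class`.
#' @export
parse_protein_change <- function(protein) {
  if (length(protein) != 1L || is.na(protein) || !nzchar(protein)) {
    stop("protein change must be a non-empty string", call. = FALSE)
  }
  p <- trimws(protein)
  fail <- function() {
    stop(sprintf("cannot parse protein change: '%s'", protein), call. = FALSE)
  }
  if (p %in% c("p.?", "p.(?)", "?")) {
    return(list(ref = "NA", mut = "NA", prot_class = 0L))
  }
  if (p %in% c("p.(=)", "p.=")) {
    return(list(ref = "NA", mut = "NA", prot_class = 1L))
  }
  body <- sub("^p\\.", "", p)
  body <- sub("^\\((.*)\\)$", "\\1", body)  # tolerate predicted parentheses
  aa <- "([A-Za-z]{3}|[A-Z*])"
  # synonymous with stated residue: Leu422=
  m <- regmatches(body, regexec(paste0("^", aa, "[0-9]+=$"), body))[[1]]
  if (length(m) > 0L) {
    return(list(ref = normalize_aa_token(m[2]), mut = "NA", prot_class = 1L))
  }
  # range consequences: Leu747_Ala750del / dup / delinsXxx
  m <- regmatches(body, regexec(
    paste0("^", aa, "[0-9]+_", aa, "[0-9]+(delins[A-Za-z*]+|del|dup)$"),
    body))[[1]]
  if (length(m) > 0L) {
    mut <- if (m[4] == "dup") "dup" else "del"
    return(list(ref = normalize_aa_token(m[2]), mut = mut, prot_class = 2L))
  }
  # single-site frameshift: Lys385fs, Lys385IlefsTer12, Arg123GlyfsTer5
  m <- regmatches(body, regexec(
    paste0("^", aa, "[0-9]+([A-Za-z]{3})?fs(Ter[0-9*]*)?$"), body))[[1]]
  if (length(m) > 0L) {
    return(list(ref = normalize_aa_token(m[2]), mut = "fs", prot_class = 2L))
  }
  # single-site del / dup / delins: Gly104del, Glu746dup, Leu747delinsPro
  m <- regmatches(body, regexec(
    paste0("^", aa, "[0-9]+(delins[A-Za-z*]+|del|dup)$"), body))[[1]]
  if (length(m) > 0L) {
    mut <- if (m[3] == "dup") "dup" else "del"
    return(list(ref = normalize_aa_token(m[2]), mut = mut, prot_class = 2L))
  }
  # plain substitution or stop gain: Lys385Thr, Ser1518Ter, V617F, W26*
  m <- regmatches(body, regexec(
    paste0("^", aa, "[0-9]+([A-Za-z]{3}|[A-Z*])$"), body))[[1]]
  if (length(m) > 0L) {
    ref <- normalize_aa_token(m[2])
    mut <- normalize_aa_token(m[3])
    if (ref %in% c("fs", "del", "dup")) fail()
    return(list(ref = ref, mut = mut, prot_class = 2L))
  }
  fail()
}

#' Encode a variant-type token
#'
#' @param token `"SNV"`, `"MNV"` or `"INDEL"` (case-insensitive).
#' @return 0, 1 or 2.
#' @export
encode_variant_type <- function(token) {
  code <- c(SNV = 0L, MNV = 1L, INDEL = 2L)[toupper(token)]
  if (length(code) != 1L || is.na(code)) {
    stop(sprintf("unknown variant type: '%s'", token), call. = FALSE)
  }
  unname(code)
}

#' Encode a minor allele frequency
#'
#' Absence of a population frequency is itself informative (rare alleles are
#' more often pathogenic) and is encoded as the sentinel -1.
#'
#' @param maf frequency in \[0,1\] or `NA`.
#' @return the frequency, or -1 when absent.
#' @export
encode_maf <- function(maf) {
  if (length(maf) != 1L) {
    stop("maf must be a scalar", call. = FALSE)
  }
  if (is.na(maf)) {
    return(-1)
  }
  if (!is.numeric(maf) || maf < 0 || maf > 1) {
    stop(sprintf("maf out of range [0,1]: %s", format(maf)), call. = FALSE)
  }
  as.numeric(maf)
}

#' Encode a variant-effect token
#'
#' @param token one of `frameshift`, `missense`, `nonsense`, `synonymous`,
#'   `unknown` (case-insensitive).
#' @return integer code (synonymous 0, missense 1, nonsense 2, frameshift 3,
#'   unknown -1).
#' @export
encode_variant_effect <- function(token) {
  code <- c(frameshift = 3L, missense = 1L, nonsense = 2L, synonymous = 0L,
            unknown = -1L)[tolower(token)]
  if (length(code) != 1L || is.na(code)) {
    stop(sprintf("unknown variant effect: '%s'", token), call. = FALSE)
  }
  unname(code)
}

#' Encode a chromosome label
#'
#' @param chrom `"1"`–`"22"`, `"X"` or `"Y"`, with or without a `chr` prefix.
#' @return integer code (X = 23, Y = 24).
#' @export
encode_chromosome <- function(chrom) {
  if (length(chrom) != 1L || is.na(chrom)) {
    stop("chromosome label must be a scalar", call. = FALSE)
  }
  lab <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  if (lab == "X") return(23L)
  if (lab == "Y") return(24L)
  n <- suppressWarnings(as.integer(lab))
  if (is.na(n) || n < 1L || n > 22L) {
    stop(sprintf("unsupported chromosome label: '%s'", chrom), call. = FALSE)
  }
  n
}

#' Encode one variant record as the 14-feature vector
#'
#' Applies the encoders for variant type, protein consequence, amino-acid
#' indices, polarity codes, Grantham distance, MAF sentinel, and
#' variant-effect class. When the consequence is not an amino-acid change
#' (`prot_class` 0 or 1) the residue-level features carry sentinels:
#' `aarefbin`/`aamutbin` 0, polarity codes 0.0, `Grantham` -1. A synonymous
#' consequence with a stated residue keeps its reference-side identity.
#'
#' @param record one-row data.frame (or list) with the record fields.
#' @param dialect a [codec_dialect()] (controls optional coverage
#'   binarization).
#' @return named numeric vector of the 14 features, plus `isMut` when the
#'   record carries a label.
#' @export
build_feature_vector <- function(record, dialect = codec_dialect()) {
  rec <- as.list(record)
  need <- setdiff(RECORD_COLUMNS, "maf")
  for (f in need) {
    if (is.null(rec[[f]]) || length(rec[[f]]) != 1L || is.na(rec[[f]])) {
      stop(sprintf("record field '%s' is missing (gene %s pos %s)", f,
                   if (is.null(rec$gene)) "?" else rec$gene,
                   if (is.null(rec$pos)) "?" else format(rec$pos)),
           call. = FALSE)
    }
  }
  if (rec$exon < 0 || rec$coverage < 0 || rec$vaf < 0 || rec$vaf > 1) {
    stop(sprintf("record fails range invariants (gene %s pos %s)",
                 rec$gene, format(rec$pos)), call. = FALSE)
  }
  pc <- parse_protein_change(rec$protein)
  is_change <- pc$prot_class == 2L
  aaref <- if (pc$ref == "NA") 0L else encode_aa_index(pc$ref, "ref")
  aamut <- if (!is_change || pc$mut == "NA") 0L else
    encode_aa_index(pc$mut, "mut")
  coverage <- as.numeric(rec$coverage)
  if (!is.na(dialect$binarize_coverage)) {
    coverage <- as.numeric(coverage >= dialect$binarize_coverage)
  }
  maf <- if (is.null(rec$maf)) NA_real_ else rec$maf
  out <- c(
    chr = as.numeric(encode_chromosome(rec$chrom)),
    POS = as.numeric(rec$pos),
    TypeBin = as.numeric(encode_variant_type(rec$variant_type)),
    Exon = as.numeric(rec$exon),
    Freq = as.numeric(rec$vaf),
    MAFbin = encode_maf(maf),
    Coverage = coverage,
    Protbin = as.numeric(pc$prot_class),
    aarefbin = as.numeric(aaref),
    aamutbin = as.numeric(aamut),
    aarefChemical = if (pc$ref == "NA") 0.0 else chemical_value(pc$ref),
    aamutChemicalVal = if (!is_change || pc$mut == "NA") 0.0 else
      chemical_value(pc$mut),
    Grantham = if (is_change) grantham_distance(pc$ref, pc$mut) else -1,
    varEffectBin = as.numeric(encode_variant_effect(rec$effect))
  )
  if (!is.null(rec$label) && !is.na(rec$label)) {
    lab <- as.numeric(rec$label)
    if (!lab %in% c(0, 1)) {
      stop(sprintf("label must be 0 or 1, got %s", format(lab)),
           call. = FALSE)
    }
    out <- c(out, isMut = lab)
  }
  out
}

#' Encode a table of variant records
#'
#' Vectorized [build_feature_vector()] with aggregated error reporting: if
#' any rows fail, the error message lists every failing row and its reason.
#'
#' @param records data.frame of variant records.
#' @param dialect a [codec_dialect()].
#' @return data.frame with the 14 feature columns, plus `isMut` when every
#'   record is labeled.
#' @export
build_feature_table <- function(records, dialect = codec_dialect()) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  rows <- vector("list", nrow(records))
  errors <- character()
  for (i in seq_len(nrow(records))) {
    res <- tryCatch(build_feature_vector(records[i, , drop = FALSE], dialect),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("row %d: %s", i, conditionMessage(res)))
    } else {
      rows[[i]] <- res
    }
  }
  if (length(errors) > 0L) {
    stop(sprintf("%d record(s) failed encoding:\n%s", length(errors),
                 paste(errors, collapse = "\n")), call. = FALSE)
  }
  labeled <- vapply(rows, function(r) "isMut" %in% names(r), logical(1))
  if (any(labeled) && !all(labeled)) {
    stop("records are partially labeled; label all rows or none",
         call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
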