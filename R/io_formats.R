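## Readers/writers for the pipeline's exchange formats and the command-line
## driver. Internal coordinates are 1-based inclusive everywhere (the
## VCF/GFF native convention); BED input is 0-based half-open and converted
## at the boundary. Logging goes to stderr, results to files only.

#' Read a TSV table
#'
#' Tab-delimited, header row, UTF-8, `.` for missing values.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  read.delim(path, sep = "\t", na.strings = ".", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a TSV table
#'
#' @param df data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read variant calls from a VCF 4.2 file
#'
#' Positions are 1-based and preserved as-is; multiallelic records are
#' passed through intact (splitting is the filter module's job), with
#' `alt` a comma-joined allele list. The INFO keys `DP` (total depth) and
#' `AF` (allele frequency) are required; the orientation-stratified count
#' keys `SRF, SAF, SRR, SAR` (ref/alt by forward/reverse stratum) and
#' `SC`/`REP` (subculture, replicate) are read when present.
#'
#' @param path VCF file path.
#' @return data.frame with columns `chrom, pos, ref, alt, qual, filters`
#'   (`""` for PASS), `depth, af` and, when present, `fwd_ref, fwd_alt,
#'   rev_ref, rev_alt, subculture, replicate`.
#' @export
readVcfCalls <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  for (key in c("DP", "AF"))
    if (!key %in% colnames(info))
      stop(sprintf("VCF is missing required INFO key '%s'", key))
  rr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(altList, function(a) paste(as.character(a), collapse = ","),
                character(1))
  flt <- rr$FILTER
  flt[flt %in% c("PASS", ".")] <- ""
  af <- info$AF
  if (is(af, "List") || is.list(af))
    af <- vapply(af, function(v) paste(v, collapse = ","), character(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    qual = ifelse(is.na(rr$QUAL), 0, rr$QUAL),
    filters = flt,
    depth = info$DP,
    af = af,
    stringsAsFactors = FALSE)
  optional <- c(fwd_ref = "SRF", fwd_alt = "SAF", rev_ref = "SRR",
                rev_alt = "SAR", subculture = "SC", replicate = "REP")
  for (col in names(optional)) {
    key <- optional[[col]]
    if (key %in% colnames(info)) {
      v <- info[[key]]
      if (is(v, "List") || is.list(v))
        v <- vapply(v, function(x) paste(x, collapse = ","), character(1))
      out[[col]] <- v
    }
  }
  nAlt <- lengths(altList)
  if (all(nAlt == 1L)) {
    for (col in intersect(c("af", "fwd_alt", "rev_alt"), names(out)))
      out[[col]] <- as.numeric(out[[col]])
  }
  rownames(out) <- NULL
  out
}

#' Write variant calls as VCF 4.2
#'
#' Emits a VCF 4.2 file whose FILTER column carries the cascade's label
#' vocabulary (`PASS` when the label set is empty) and whose INFO fields
#' hold depth, allele frequency, the orientation-stratified counts
#' (`SRF/SAF/SRR/SAR`) and the subculture/replicate keys, so the file
#' round-trips through [readVcfCalls()].
#'
#' @param calls data.frame of calls ([consensusCall()] layout, or any
#'   frame with `chrom, pos, ref, alt`; other columns are optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfCalls <- function(calls, path) {
  labelDefs <- vapply(FILTER_LABELS, function(l)
    sprintf('##FILTER=<ID=%s,Description="%s">', l,
            switch(l,
                   low_qual = "Phred site score below threshold",
                   no_consensus = "failed consensus criterion B",
                   low_orientation_af = "AF not above threshold in both orientations",
                   low_reads = "insufficient reads or base quality",
                   rrna = "position in excluded rRNA region",
                   starter_background = "present in starter culture above threshold",
                   insufficient_recurrence = "too few subcultures above recurrence AF",
                   depth_artifact = "AF correlated with sequencing depth")),
    character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=degeneR",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=SRF,Number=1,Type=Integer,Description="Reference reads, first-forward stratum">',
    '##INFO=<ID=SAF,Number=A,Type=Integer,Description="Alternate reads, first-forward stratum">',
    '##INFO=<ID=SRR,Number=1,Type=Integer,Description="Reference reads, first-reverse stratum">',
    '##INFO=<ID=SAR,Number=A,Type=Integer,Description="Alternate reads, first-reverse stratum">',
    '##INFO=<ID=SC,Number=1,Type=Integer,Description="Subculture index">',
    '##INFO=<ID=REP,Number=1,Type=Integer,Description="Replicate id">',
    labelDefs,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  getCol <- function(nm, default = NULL) {
    if (nm %in% names(calls)) calls[[nm]] else default
  }
  n <- nrow(calls)
  qual <- getCol("qual", rep(".", n))
  filters <- getCol("filters", rep("", n))
  filters <- ifelse(is.na(filters) | !nzchar(filters), "PASS", filters)
  fmt <- function(x) {
    ifelse(is.na(x), ".", formatC(x, format = "fg", digits = 8))
  }
  infoParts <- list()
  depth <- getCol("depth")
  if (is.null(depth) && all(c("depth_fwd", "depth_rev") %in% names(calls)))
    depth <- calls$depth_fwd + calls$depth_rev
  if (is.null(depth) &&
      all(c("fwd_ref", "fwd_alt", "rev_ref", "rev_alt") %in% names(calls)))
    depth <- calls$fwd_ref + calls$fwd_alt + calls$rev_ref + calls$rev_alt
  if (!is.null(depth)) infoParts$DP <- paste0("DP=", depth)
  af <- getCol("af")
  if (!is.null(af)) infoParts$AF <- paste0("AF=", vapply(
    as.character(af), function(a) a, character(1)))
  pairs <- c(SRF = "fwd_ref", SAF = "fwd_alt", SRR = "rev_ref",
             SAR = "rev_alt", SC = "subculture", REP = "replicate")
  for (key in names(pairs)) {
    v <- getCol(pairs[[key]])
    if (!is.null(v)) infoParts[[key]] <- paste0(key, "=", v)
  }
  info <- if (length(infoParts)) do.call(paste, c(infoParts, sep = ";"))
          else rep(".", n)
  records <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                   ifelse(is.na(suppressWarnings(as.numeric(qual))), ".",
                          fmt(suppressWarnings(as.numeric(qual)))),
                   filters, info, sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read exclusion regions from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the internal
#' 1-based inclusive convention and overlapping intervals are merged.
#'
#' @param path BED file path (3+ columns).
#' @return `GRanges` of merged exclusion intervals (empty for an empty
#'   file).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr\t9\t20", f)
#' readBedRegions(f)  # [10, 20]
#' @export
readBedRegions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GenomicRanges::GRanges())
  raw <- read.delim(text = lines, header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED parse error: fewer than 3 columns")
  if (!is.numeric(raw[[2]]) || !is.numeric(raw[[3]]))
    stop("BED parse error: non-numeric coordinates")
  if (any(raw[[2]] >= raw[[3]]))
    stop("BED parse error: start >= end")
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(gr)
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` features (1-based inclusive coordinates as-is), extracts
#' `gene_id` from the `ID` attribute and retains strand and product.
#' Non-gene features are skipped with a logged count on stderr.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id, chrom, start, end, strand,
#'   product`.
#' @export
readGffGenes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  isGene <- as.character(gr$type) == "gene"
  nSkipped <- sum(!isGene)
  if (nSkipped)
    message(sprintf("readGffGenes: skipped %d non-gene feature(s)",
                    nSkipped))
  gr <- gr[isGene]
  ids <- gr$ID
  if (is.null(ids) || any(is.na(ids) | !nzchar(ids))) {
    offending <- if (is.null(ids)) seq_along(gr) else
      which(is.na(ids) | !nzchar(ids))
    stop("GFF3 gene feature(s) missing ID attribute at record(s): ",
         paste(offending, collapse = ", "))
  }
  product <- if (!is.null(gr$product)) gr$product else
    rep(NA_character_, length(gr))
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             product = product, stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame in the [readGffGenes()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGffGenes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  if (!is.null(genes$product)) gr$product <- genes$product
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' The file may define `seed` and sections `regime`, `seq` and `filter`
#' whose entries override the corresponding constructor defaults; `flags`
#' passed by the CLI override the file.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`), or `NULL`
#'   for all defaults.
#' @param overrides named list applied on top of the file values.
#' @return List with `seed`, `regime` ([RegimeConfig-class]), `seq`
#'   ([SeqParams-class]), `filter` ([FilterParams-class]) and `raw` (the
#'   resolved flat configuration).
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  for (section in names(overrides)) {
    if (is.list(overrides[[section]])) {
      for (nm in names(overrides[[section]]))
        cfg[[section]][[nm]] <- overrides[[section]][[nm]]
    } else cfg[[section]] <- overrides[[section]]
  }
  build <- function(ctor, values) do.call(ctor, as.list(values))
  list(seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       regime = build(regimeConfig, cfg$regime),
       seq = build(seqParams, cfg$seq),
       filter = build(filterParams, cfg$filter),
       raw = cfg)
}

#' Write a run manifest
#'
#' Serializes the resolved configuration, seed and package version to
#' JSON so a run can be reproduced exactly.
#'
#' @param config resolved configuration list ([readRunConfig()] output).
#' @param path output JSON path.
#' @param extra named list of additional fields.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "degeneR",
    version = as.character(utils::packageVersion("degeneR")),
    seed = config$seed,
    regime = s4ToList(config$regime),
    seq = s4ToList(config$seq),
    filter = s4ToList(config$filter)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

s4ToList <- function(obj) {
  nms <- methods::slotNames(class(obj))
  setNames(lapply(nms, function(nm) slot(obj, nm)), nms)
}
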