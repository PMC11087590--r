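# Readers/writers for the standard formats the pipeline touches.
# Internal convention everywhere: 0-based half-open coordinates; GFF (1-based
# inclusive) and VCF (1-based positions) are converted at the boundary only.

#' Read a gene annotation from GFF3/GTF
#'
#' Keeps `gene` feature rows, converts 1-based inclusive file coordinates to
#' 0-based half-open, and computes the strand-correct TSS (start on `+`,
#' end-1 on `-`, both in internal coordinates). Chromosome lengths are taken
#' from `##sequence-region` pragmas when present.
#'
#' @param path Path to a GFF3 or GTF file containing gene features.
#' @return A `GenomeAnnotation`: list with `chromosomes` (named lengths, bp,
#'   possibly `NA` when no pragma was present) and `genes` (data.frame with
#'   gene_id, chrom, strand, start, end, tss).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  if (!length(body)) stop("no feature lines in ", path)
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  bad <- body[nfield != 9]
  if (length(bad)) {
    stop(sprintf("malformed annotation line %d in %s (expected 9 tab-separated fields)",
                 bad[1], path))
  }
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  if (!length(gr)) stop("no gene feature lines present in ", path)
  mc <- S4Vectors::mcols(gr)
  gid <- if (!is.null(mc$gene_id)) as.character(mc$gene_id)
         else if (!is.null(mc$ID)) as.character(mc$ID)
         else stop("gene features carry neither gene_id nor ID attributes")
  if (anyNA(gid)) stop("gene feature without an id")
  if (anyDuplicated(gid)) {
    stop("duplicate gene_id: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }
  chroms <- parse_sequence_regions(raw)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("gene without explicit strand")
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  known <- chrom %in% names(chroms)
  over <- known & end0 > chroms[chrom]
  if (any(over)) {
    stop("gene ", gid[which(over)[1]], " extends beyond the length of ",
         chrom[which(over)[1]])
  }
  genes <- data.frame(
    gene_id = gid, chrom = chrom, strand = strand,
    start = start0, end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    stringsAsFactors = FALSE)
  genome_annotation(chromosomes = chroms, genes = genes)
}

parse_sequence_regions <- function(lines) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(trimws(sr), "\\s+")
  stats::setNames(vapply(parts, function(p) as.numeric(p[4]), 0),
                  vapply(parts, function(p) p[2], ""))
}

#' Construct/validate a GenomeAnnotation
#'
#' @param chromosomes Named numeric vector of chromosome lengths (bp). May be
#'   empty when lengths are unknown.
#' @param genes data.frame with gene_id, chrom, strand, start, end, tss
#'   (0-based half-open; tss is a 0-based position).
#' @return A validated `GenomeAnnotation` object.
#' @export
genome_annotation <- function(chromosomes, genes) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "tss")
  stopifnot(all(need %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    stop("gene intervals must satisfy 0 <= start < end")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  exp_tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (any(genes$tss != exp_tss)) stop("tss inconsistent with strand convention")
  known <- genes$chrom %in% names(chromosomes)
  if (any(known & genes$end > chromosomes[genes$chrom])) {
    stop("gene interval exceeds chromosome length")
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "GenomeAnnotation")
}

#' Write a GenomeAnnotation as GFF3
#'
#' @param ann A `GenomeAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  g <- ann$genes
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(ann$chromosomes),
                   as.integer(ann$chromosomes)))
  rows <- sprintf("%s\thypoxlink\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
                  g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a BED3+ file as an IntervalSet
#'
#' BED's native 0-based half-open coordinates are preserved. Ids are taken
#' from column 4 when present, otherwise generated as `<role>_<n>`.
#' Overlapping records are accepted (a peak or gene may belong to more than
#' one TAD downstream); a message flags them.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @param role One of `"TAD"`, `"peak"`, `"window"`, `"region"`.
#' @param chromosomes Optional named lengths; records on unknown chromosomes
#'   trigger a warning but are kept.
#' @return An `IntervalSet`: data.frame (chrom, start, end, id, score) with a
#'   `role` attribute.
#' @export
read_bed <- function(path, role = c("region", "TAD", "peak", "window"),
                     chromosomes = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE)
  nm <- if (!is.null(gr$name)) as.character(gr$name) else names(gr)
  df$id <- if (!is.null(nm) && !anyNA(nm) && all(nzchar(nm))) nm
           else sprintf("%s_%d", role, seq_len(nrow(df)))
  df$score <- if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  interval_set(df, role = role, chromosomes = chromosomes)
}

#' Construct/validate an IntervalSet
#'
#' @param records data.frame with chrom, start, end, id (0-based half-open)
#'   and optional score.
#' @param role Role tag for the set.
#' @param chromosomes Optional named chromosome lengths for a soft check.
#' @return A validated `IntervalSet`.
#' @export
interval_set <- function(records, role = c("region", "TAD", "peak", "window"),
                         chromosomes = NULL) {
  role <- match.arg(role)
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(records)))
  if (!"score" %in% names(records)) records$score <- NA_real_
  if (any(records$start < 0)) stop("negative interval start")
  if (any(records$start >= records$end)) {
    stop("interval with start >= end (0-based half-open expected)")
  }
  if (anyDuplicated(records$id)) stop("interval ids must be unique within a set")
  if (!is.null(chromosomes)) {
    unk <- setdiff(unique(records$chrom), names(chromosomes))
    if (length(unk)) {
      warning("intervals on chromosome(s) absent from annotation: ",
              paste(unk, collapse = ", "), " (records kept)")
    }
  }
  n_olap <- overlap_count(records)
  if (n_olap > 0) {
    message(sprintf("interval set '%s': %d overlapping record pair(s) accepted",
                    role, n_olap))
  }
  rownames(records) <- NULL
  structure(records[, c("chrom", "start", "end", "id", "score")],
            role = role, class = c("IntervalSet", "data.frame"))
}

overlap_count <- function(records) {
  gr <- GenomicRanges::GRanges(records$chrom,
                               IRanges::IRanges(records$start + 1L, records$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  length(hits)
}

#' Write an IntervalSet as BED
#'
#' @param x An `IntervalSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "IntervalSet"))
  has_score <- !all(is.na(x$score))
  cols <- data.frame(x$chrom, x$start, x$end, x$id)
  if (has_score) cols$score <- x$score
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a biallelic-SNP subset of a VCF
#'
#' Multiallelic and non-SNP records are skipped (counts reported via
#' `message`). Genotypes are stored as alt-allele dosage 0/1/2 with `NA` for
#' missing calls.
#'
#' @param path Path to a VCF (v4.x) file with a GT FORMAT field.
#' @param populations Optional named character vector mapping sample id to
#'   population label.
#' @return A `GenotypeMatrix`: list with `variants` (chrom, pos 1-based, ref,
#'   alt), `geno` (variants x samples dosage matrix), `samples`,
#'   `populations`.
#' @export
read_vcf_subset <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!any(startsWith(readLines(path, n = 200L), "#CHROM"))) {
    stop("missing #CHROM header line in ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$ALT %in% c("A", "C", "G", "T") & fix$REF %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("read_vcf_subset: skipped %d multiallelic/non-SNP record(s)",
                    n_skip))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dose <- gt_to_dosage(gt)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, dose, populations)
}

gt_to_dosage <- function(gt) {
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[clean %in% c("0/0")] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean %in% c("1/1")] <- 2
  dose
}

#' Construct/validate a GenotypeMatrix
#'
#' @param variants data.frame with chrom, pos (1-based), ref, alt.
#' @param geno Numeric matrix of alt-allele dosages (0/1/2/NA), one row per
#'   variant, one column per sample (named).
#' @param populations Optional named character vector (sample -> population).
#' @return A `GenotypeMatrix` object.
#' @export
genotype_matrix <- function(variants, geno, populations = NULL) {
  stopifnot(is.matrix(geno), nrow(variants) == nrow(geno))
  if (is.null(colnames(geno))) stop("genotype matrix must have sample names")
  if (!all(geno %in% c(0, 1, 2) | is.na(geno))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (!is.null(populations)) {
    miss <- setdiff(colnames(geno), names(populations))
    if (length(miss)) {
      stop("samples without population label: ", paste(miss, collapse = ", "))
    }
    populations <- populations[colnames(geno)]
  }
  structure(list(variants = variants, geno = geno,
                 samples = colnames(geno), populations = populations),
            class = "GenotypeMatrix")
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits only what [read_vcf_subset()] consumes: biallelic SNP rows with a GT
#' FORMAT field; dosage 1 is written as `0/1`, missing as `./.`.
#'
#' @param g A `GenotypeMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_subset <- function(g, path) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples), collapse = "\t"))
  gtchr <- matrix("./.", nrow(g$geno), ncol(g$geno))
  gtchr[!is.na(g$geno) & g$geno == 0] <- "0/0"
  gtchr[!is.na(g$geno) & g$geno == 1] <- "0/1"
  gtchr[!is.na(g$geno) & g$geno == 2] <- "1/1"
  rows <- paste(g$variants$chrom, g$variants$pos, ".", g$variants$ref,
                g$variants$alt, ".", "PASS", ".", "GT",
                apply(gtchr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a TSV matrix with sample metadata into an OmicsMatrix
#'
#' Leading `#` comment lines (provenance headers) are ignored. The metadata
#' join must be total: every matrix sample needs a metadata row.
#'
#' @param path TSV with a feature-id first column and sample ids as header.
#' @param metadata_path TSV of sample metadata keyed by `sample_id`.
#' @param unit Declared unit of the values (see [omics_matrix()]).
#' @return An `OmicsMatrix`.
#' @export
read_matrix_tsv <- function(path, metadata_path, unit) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  meta <- utils::read.delim(metadata_path, comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
  omics_matrix(values, unit, meta)
}

#' Write an OmicsMatrix (and its metadata) as TSV with a provenance header
#'
#' Values are serialized with `%.17g` so a write/read round trip is
#' bit-identical.
#'
#' @param om An `OmicsMatrix`.
#' @param path Output path for the matrix.
#' @param metadata_path Optional output path for the sample metadata.
#' @param provenance Named list echoed as `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(om, path, metadata_path = NULL,
                             provenance = list()) {
  stopifnot(inherits(om, "OmicsMatrix"))
  prov <- c(sprintf("# hypoxlink %s matrix", om$unit),
            sprintf("# %s: %s", names(provenance),
                    vapply(provenance, function(x) paste(format(x), collapse = ","), "")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  writeLines(paste(c("feature_id", colnames(om$values)), collapse = "\t"), con)
  body <- apply(om$values, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(om$values), body, sep = "\t"), con)
  if (!is.null(metadata_path)) {
    utils::write.table(om$meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write any result table as TSV with a provenance header
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param provenance Named list echoed as `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hypoxlink result",
               sprintf("# %s: %s", names(provenance),
                       vapply(provenance, function(x) paste(format(x), collapse = ","), ""))),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
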