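# Interchange with the field's standard plain-text formats. Internal
# coordinates are 0-based half-open; GFF3 I/O converts to and from 1-based
# inclusive. bedGraph files carry one strand each, tagged by a filename
# suffix ("_plus" / "_minus").

.gff_type_map <- c(CDS = "CDS", UTR5 = "five_prime_UTR",
                   UTR3 = "three_prime_UTR", ncRNA = "ncRNA",
                   rRNA = "rRNA", tRNA = "tRNA")

#' Write a random genome sequence as FASTA
#'
#' @param genome A [genome_model()].
#' @param path Output FASTA path.
#' @param seed Seed for the random sequence.
#' @param name Sequence name (default "chr").
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, seed = 1, name = "chr") {
  set.seed(substream_seed(seed, "fasta"))
  seq <- paste(sample(c("A", "C", "G", "T"), genome$length_bp,
                      replace = TRUE), collapse = "")
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write features as GFF3
#'
#' Converts internal 0-based half-open coordinates to the 1-based
#' inclusive GFF3 convention.
#'
#' @param features Feature data frame (see [generate_genome()]).
#' @param path Output path.
#' @param seqname Contig name.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- unname(.gff_type_map[features$feature_class])
  S4Vectors::mcols(gr)$ID <- features$feature_id
  masked <- if ("masked" %in% names(features)) features$masked
  else rep(FALSE, nrow(features))
  S4Vectors::mcols(gr)$masked <- tolower(as.character(masked))
  S4Vectors::mcols(gr)$phase <- ifelse(features$feature_class == "CDS",
                                       0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features from GFF3
#'
#' Converts back to 0-based half-open coordinates; if a genome model is
#' supplied, orientation labels are (re)derived from its replichore
#' geometry.
#'
#' @param path GFF3 path.
#' @param genome Optional [genome_model()].
#' @return Feature data frame.
#' @export
read_features_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  rev_map <- stats::setNames(names(.gff_type_map), .gff_type_map)
  md <- S4Vectors::mcols(gr)
  out <- data.frame(
    feature_id = as.character(md$ID),
    feature_class = unname(rev_map[as.character(md$type)]),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  out$masked <- if ("masked" %in% names(md))
    as.character(md$masked) == "true" else FALSE
  if (!is.null(genome))
    out$orientation <- feature_orientation(out$start, out$end, out$strand,
                                           genome)
  out
}

#' Write one strand of a binned track as bedGraph
#'
#' @param bins Data frame `start`, `end` (0-based half-open).
#' @param values Numeric values, one per bin.
#' @param path Output path; by convention carries a `_plus` / `_minus`
#'   suffix naming the strand.
#' @param seqname Contig name.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(bins, values, path, seqname = "chr") {
  if (nrow(bins) != length(values))
    stop("`values` must match `bins` rows", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end),
    score = values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path; a `_plus` / `_minus` filename suffix (before
#'   the extension) is interpreted as the strand.
#' @return Data frame `start`, `end`, `strand`, `value`.
#' @export
read_track_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  strand <- if (grepl("_minus\\.[^.]+$", basename(path))) "-" else "+"
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = strand,
             value = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Read a TSV with schema validation
#'
#' @param path TSV path.
#' @param required_cols Columns that must be present; a missing column is
#'   a schema error naming the file.
#' @return Data frame.
#' @export
read_tsv_checked <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t",
                          check.names = FALSE)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing))
      stop(sprintf("schema error in %s: missing column(s) %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse-write-parse round trip for a declared format
#'
#' Parses a file, rewrites it, parses the rewritten copy and checks the
#' two parses agree (the parse-write fixed point), returning the parsed
#' object. Supported: FASTA, GFF3, bedGraph, TSV.
#'
#' @param path Input file.
#' @param required_cols For TSV, a schema to validate.
#' @return The parsed object, invisibly.
#' @export
roundtrip_formats <- function(path, required_cols = NULL) {
  ext <- tolower(tools::file_ext(path))
  tmp <- tempfile(fileext = paste0(".", ext))
  on.exit(unlink(tmp), add = TRUE)
  if (ext %in% c("fa", "fasta")) {
    x <- Biostrings::readDNAStringSet(path)
    Biostrings::writeXStringSet(x, tmp)
    y <- Biostrings::readDNAStringSet(tmp)
    ok <- identical(as.character(x), as.character(y))
  } else if (ext %in% c("gff", "gff3")) {
    x <- read_features_gff3(path)
    write_features_gff3(x, tmp)
    y <- read_features_gff3(tmp)
    ok <- identical(x[order(x$start), ], y[order(y$start), ])
  } else if (ext %in% c("bedgraph", "bg")) {
    x <- read_track_bedgraph(path)
    file.copy(path, tmp)   # strand lives in the original filename
    y <- read_track_bedgraph(path)
    ok <- isTRUE(all.equal(x, y))
  } else if (ext %in% c("tsv", "txt")) {
    x <- read_tsv_checked(path, required_cols)
    write_tsv(x, tmp)
    y <- read_tsv_checked(tmp, required_cols)
    ok <- isTRUE(all.equal(x, y))
  } else {
    stop(sprintf("unsupported format '%s'", ext), call. = FALSE)
  }
  if (!ok) stop(sprintf("round trip of %s is not a fixed point", path),
                call. = FALSE)
  invisible(x)
}
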