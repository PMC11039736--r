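# Readers/writers for the external formats the pipeline touches.
# All genomic coordinates are 0-based half-open (BED convention); GTF/GFF
# input is converted on read.

#' Read a per-base score track
#'
#' @param path file path.
#' @param dialect `"bedgraph"` (text) or `"bigwig"` (binary, via rtracklayer).
#' @param chrom_lengths optional named integer vector of chromosome lengths;
#'   for bedGraph input the default length of each chromosome is the largest
#'   end coordinate seen.
#' @return A [score_track].
#' @details Overlapping bedGraph records are a validation error; intervals are
#'   expanded to dense per-base vectors with gaps filled by 0.
#' @export
read_score_track <- function(path, dialect = c("bedgraph", "bigwig"),
                             chrom_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bigwig") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("BigWig support requires the 'rtracklayer' package")
    cov <- rtracklayer::import(path, as = "RleList")
    return(score_track(lapply(as.list(cov), as.numeric)))
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  recs <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- which(keep)
  bad <- which(lengths(recs) < 4L)
  if (length(bad))
    stop("malformed bedGraph record at line ", lineno[bad[1L]], " of ", path)
  chrom <- vapply(recs, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(recs, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(recs, `[[`, "", 3L)))
  val <- suppressWarnings(as.numeric(vapply(recs, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(val) | start < 0 | start >= end)
  if (length(bad))
    stop("invalid bedGraph record at line ", lineno[bad[1L]], " of ", path)
  chroms <- unique(chrom)
  lens <- vapply(chroms, function(ch) {
    len <- max(end[chrom == ch])
    if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      if (len > chrom_lengths[[ch]])
        stop("bedGraph record exceeds declared length of ", ch)
      len <- as.integer(chrom_lengths[[ch]])
    }
    len
  }, integer(1))
  vecs <- lapply(chroms, function(ch) {
    i <- which(chrom == ch)
    i <- i[order(start[i])]
    if (any(end[i][-length(i)] > start[i][-1L]))
      stop("overlapping bedGraph records on ", ch, " in ", path)
    v <- numeric(lens[[ch]])
    for (j in i) v[(start[j] + 1L):end[j]] <- val[j]
    v
  })
  names(vecs) <- chroms
  score_track(vecs)
}

#' Write a score track
#'
#' bedGraph output emits one record per non-zero run (all-zero chromosomes
#' produce no records) and round-trips bit-exactly; BigWig round-trips within
#' float32 precision.
#'
#' @param track a [score_track].
#' @param path output path.
#' @param dialect `"bedgraph"` or `"bigwig"`.
#' @export
write_score_track <- function(track, path, dialect = c("bedgraph", "bigwig")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "score_track"))
  if (dialect == "bigwig") {
    for (pkg in c("rtracklayer", "GenomicRanges", "IRanges",
                  "GenomeInfoDb"))
      if (!requireNamespace(pkg, quietly = TRUE))
        stop("BigWig support requires the '", pkg, "' package")
    lens <- track_chrom_lengths(track)
    grl <- lapply(names(lens), function(ch) {
      r <- rle(track[[ch]])
      ends <- cumsum(r$lengths)
      keep <- r$values != 0
      GenomicRanges::GRanges(
        ch,
        IRanges::IRanges(start = (ends - r$lengths + 1L)[keep],
                         end = ends[keep]),
        score = r$values[keep])
    })
    gr <- do.call(c, grl)
    gr <- GenomeInfoDb::`seqlengths<-`(gr, value = lens)
    rtracklayer::export(gr, path, format = "BigWig")
    return(invisible(NULL))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track_chrom_lengths(track))) {
    r <- rle(track[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(NULL)
}

#' Read a FASTA genome
#'
#' Sequences are uppercased and restricted to the alphabet {A, C, G, T, N};
#' IUPAC ambiguity codes are mapped to N.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(ss)))
    stop("duplicate sequence names in ", path)
  seqs <- toupper(as.character(ss))
  # collapse IUPAC ambiguity codes to N
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(NULL)
}

#' Extract interval sequences from a genome
#'
#' Minus-strand intervals are reverse-complemented.
#'
#' @param genome named character vector (chromosome name -> sequence).
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return Character vector of sequences, one per interval.
#' @export
extract_sequences <- function(genome, intervals) {
  check_intervals(intervals)
  strand <- intervals$strand %||% rep(".", nrow(intervals))
  vapply(seq_len(nrow(intervals)), function(i) {
    ch <- intervals$chrom[i]
    if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
    if (intervals$start[i] < 0 || intervals$end[i] > nchar(genome[[ch]]))
      stop(sprintf("interval %s:%d-%d out of bounds (length %d)",
                   ch, intervals$start[i], intervals$end[i],
                   nchar(genome[[ch]])))
    s <- substr(genome[[ch]], intervals$start[i] + 1L, intervals$end[i])
    if (strand[i] == "-") revcomp(s) else s
  }, character(1))
}

check_intervals <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("intervals must be a data.frame with chrom/start/end columns")
  if (nrow(x) && any(x$start >= x$end))
    stop("interval with start >= end at row ", which(x$start >= x$end)[1L])
  if (nrow(x) && any(x$start < 0)) stop("negative interval start")
  invisible(x)
}

#' Read / write BED intervals
#'
#' BED3+ with optional name, score and strand columns; missing columns are
#' filled with `"."`, `0` and `"."` so the returned frame always has six
#' columns. Coordinates stay 0-based half-open.
#'
#' @param path BED file.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  recs <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(recs) < 3L))
    stop("BED record with < 3 fields at line ", which(lengths(recs) < 3L)[1L])
  fld <- function(k, default) vapply(recs, function(r) {
    if (length(r) >= k) r[[k]] else default
  }, character(1))
  out <- data.frame(
    chrom = fld(1L, ""),
    start = as.integer(fld(2L, "0")),
    end = as.integer(fld(3L, "0")),
    name = fld(4L, "."),
    score = suppressWarnings(as.numeric(fld(5L, "0"))),
    strand = fld(6L, "."))
  if (any(is.na(out$start) | is.na(out$end)))
    stop("non-numeric BED coordinates")
  if (any(out$start >= out$end))
    stop("BED record with start >= end at line ",
         which(out$start >= out$end)[1L])
  out
}

#' @rdname read_bed
#' @param intervals data.frame with at least chrom/start/end.
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  x <- data.frame(chrom = intervals$chrom, start = intervals$start,
                  end = intervals$end,
                  name = intervals$name %||% rep(".", nrow(intervals)),
                  score = intervals$score %||% rep(0, nrow(intervals)),
                  strand = intervals$strand %||% rep(".", nrow(intervals)))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(NULL)
}

#' Read / write motif collections
#'
#' JASPAR text blocks keep counts as-is; MEME minimal probability matrices are
#' converted to counts via their `nsites`. In JASPAR headers an optional
#' tab-separated second field is read as the motif's TF-class annotation.
#'
#' @param path motif file.
#' @param format `"jaspar"` or `"meme_minimal"`.
#' @return list of [new_motif] objects.
#' @export
read_motifs <- function(path, format = c("jaspar", "meme_minimal")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "jaspar") return(parse_jaspar(lines, path))
  parse_meme_minimal(lines, path)
}

parse_jaspar <- function(lines, path) {
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR motif headers in ", path)
  bounds <- c(heads, length(lines) + 1L)
  lapply(seq_along(heads), function(i) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    fields <- strsplit(hdr, "\t", fixed = TRUE)[[1L]]
    name <- trimws(fields[1L])
    tf_class <- if (length(fields) >= 2L) trimws(fields[2L]) else NA_character_
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4L)
      stop("motif '", name, "': expected 4 count rows, got ", length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("[][]", " ", ln)
      toks <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      list(base = toks[1L], counts = suppressWarnings(as.numeric(toks[-1L])))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES))
      stop("motif '", name, "': rows must be labelled A, C, G, T")
    widths <- lengths(lapply(rows, `[[`, "counts"))
    if (length(unique(widths)) != 1L)
      stop("motif '", name, "': rows have differing widths")
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- bases
    new_motif(counts[DNA_BASES, , drop = FALSE], name = name,
              tf_class = tf_class)
  })
}

parse_meme_minimal <- function(lines, path) {
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  lapply(starts, function(s) {
    name <- strsplit(trimws(lines[s]), "[ \t]+")[[1L]][2L]
    hdr_i <- s + grep("^letter-probability matrix",
                      lines[(s + 1L):length(lines)])[1L]
    if (is.na(hdr_i)) stop("motif '", name, "': missing probability matrix")
    hdr <- lines[hdr_i]
    getnum <- function(key, default = NA_real_) {
      m <- regmatches(hdr, regexec(paste0(key, "=\\s*([0-9.eE+-]+)"), hdr))[[1L]]
      if (length(m) < 2L) default else as.numeric(m[2L])
    }
    w <- as.integer(getnum("w"))
    nsites <- getnum("nsites", 20)
    evalue <- getnum("E", NA_real_)
    if (is.na(w)) stop("motif '", name, "': matrix header lacks w=")
    rows <- lines[(hdr_i + 1L):(hdr_i + w)]
    probs <- t(vapply(rows, function(ln) {
      v <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]])
      if (length(v) != 4L)
        stop("motif '", name, "': expected 4 probabilities per row")
      v
    }, numeric(4), USE.NAMES = FALSE))
    new_motif(t(probs) * nsites, nsites = nsites, name = name, evalue = evalue)
  })
}

#' @rdname read_motifs
#' @param motifs list of motifs.
#' @param background background written to the MEME header.
#' @export
write_motifs <- function(motifs, path, format = c("jaspar", "meme_minimal"),
                         background = rep(0.25, 4)) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "jaspar") {
    for (m in motifs) {
      hdr <- paste0(">", m$name)
      if (!is.na(m$tf_class %||% NA)) hdr <- paste0(hdr, "\t", m$tf_class)
      writeLines(hdr, con)
      for (b in DNA_BASES)
        writeLines(sprintf("%s [ %s ]", b,
                           paste(sprintf("%.6g", m$counts[b, ]),
                                 collapse = " ")), con)
    }
  } else {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "", "Background letter frequencies",
                 sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                         background[2], background[3], background[4]), ""),
               con)
    for (m in motifs) {
      p <- motif_probs(m)
      writeLines(sprintf("MOTIF %s", m$name), con)
      writeLines(sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= %.6g E= %s",
        motif_width(m), m$nsites,
        if (is.na(m$evalue)) "1" else sprintf("%.3g", m$evalue)), con)
      for (j in seq_len(ncol(p)))
        writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                           p[1, j], p[2, j], p[3, j], p[4, j]), con)
      writeLines("", con)
    }
  }
  invisible(NULL)
}

#' Read genomic features from GTF/GFF
#'
#' Keeps records of the requested feature types and converts 1-based inclusive
#' coordinates to 0-based half-open. The feature name is taken from the
#' `gene_id` (GTF) or `Name`/`ID` (GFF3) attribute.
#'
#' @param path GTF or GFF3 file.
#' @param feature_types character vector of types to keep (column 3).
#' @return data.frame with chrom, start, end, strand, name.
#' @export
read_gtf_features <- function(path, feature_types = "gene") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  recs <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(recs) < 9L))
    stop("GTF/GFF record with < 9 fields at line ",
         which(lengths(recs) < 9L)[1L])
  type <- vapply(recs, `[[`, "", 3L)
  keep <- which(type %in% feature_types)
  name <- vapply(keep, function(i) {
    attrs <- recs[[i]][[9L]]
    m <- regmatches(attrs, regexec('gene_id[ =]+"?([^";]+)"?', attrs))[[1L]]
    if (length(m) < 2L)
      m <- regmatches(attrs, regexec("Name=([^;]+)", attrs))[[1L]]
    if (length(m) < 2L)
      m <- regmatches(attrs, regexec("ID=([^;]+)", attrs))[[1L]]
    if (length(m) < 2L)
      stop("feature without gene_id/Name/ID attribute: ", attrs)
    m[2L]
  }, character(1))
  data.frame(
    chrom = vapply(recs[keep], `[[`, "", 1L),
    start = as.integer(vapply(recs[keep], `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(recs[keep], `[[`, "", 5L)),
    strand = vapply(recs[keep], `[[`, "", 7L),
    name = name)
}

#' Read gene sets from GMT
#'
#' @param path GMT file (set name, description, genes...). The description
#'   field is dropped and duplicate genes within a set are removed.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(recs) < 3L))
    stop("GMT line with < 3 columns at line ", which(lengths(recs) < 3L)[1L])
  stats::setNames(lapply(recs, function(r) unique(r[-(1:2)])),
                  vapply(recs, `[[`, "", 1L))
}
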