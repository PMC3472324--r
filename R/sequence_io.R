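# Genome containers and file I/O.
#
# Coordinates are 1-based inclusive on the forward strand throughout the
# package (the GenBank/GFF3 convention), so file I/O needs no conversion.

#' Genome record constructor
#'
#' @param accession Accession or name of the replicon.
#' @param sequence DNA string over A,C,G,T,N.
#' @param features Data frame of gene features (see [gene_feature()]); sorted
#'   by `start` on construction.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(accession, sequence, features = empty_features(),
                          topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  bad <- unique(strsplit(gsub("[ACGTN]", "", sequence), "")[[1L]])
  if (length(bad)) {
    pos <- which(!strsplit(sequence, "")[[1L]] %in% c("A", "C", "G", "T", "N"))
    stop(sprintf("sequence contains non-IUPAC-core characters %s at positions %s",
                 paste(bad, collapse = ","),
                 paste(utils::head(pos, 10L), collapse = ",")))
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    L <- nchar(sequence)
    if (any(features$start < 1L) || any(features$end > L) ||
        any(features$start > features$end))
      stop("feature coordinates outside genome or inverted")
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(accession = accession, sequence = sequence,
                 topology = topology, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record %s  %s  %d bp  %d features\n",
              x$accession, x$topology, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Empty feature table
#'
#' @return Zero-row data frame with the gene-feature columns.
#' @export
empty_features <- function() {
  data.frame(feature_id = character(), locus_tag = character(),
             gene_name = character(), start = integer(), end = integer(),
             strand = character(), product = character(),
             translation = character(), source = character(),
             stringsAsFactors = FALSE)
}

#' Build one gene-feature row
#'
#' @param feature_id,locus_tag Identifiers.
#' @param start,end 1-based inclusive forward-strand coordinates.
#' @param strand `"+"` or `"-"`.
#' @param gene_name,product,translation Optional annotation (NA if absent).
#' @param source Annotation provenance label (e.g. `"genbank"`,
#'   `"naive_orf_caller"`).
#' @return One-row data frame.
#' @export
gene_feature <- function(feature_id, locus_tag, start, end, strand,
                         gene_name = NA_character_, product = NA_character_,
                         translation = NA_character_, source = "genbank") {
  stopifnot(start >= 1L, end >= start, strand %in% c("+", "-"))
  if (!is.na(translation)) {
    aa <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", translation)
    if (nchar(aa)) stop("translation contains illegal residues: ", aa)
    if (nchar(translation) < 1L) stop("translation must be non-empty when present")
  }
  data.frame(feature_id = feature_id, locus_tag = locus_tag,
             gene_name = gene_name, start = as.integer(start),
             end = as.integer(end), strand = strand, product = product,
             translation = translation, source = source,
             stringsAsFactors = FALSE)
}

# --- GenBank ------------------------------------------------------------------

# Parse a GenBank location string restricted to the forms a..b,
# complement(a..b), join(a..b,c..d) and complement(join(...)).
.parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1L]]
  spans <- do.call(rbind, lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1L]]
    if (length(m) != 3L) stop("unsupported GenBank location: ", loc)
    as.integer(m[2:3])
  }))
  list(start = min(spans[, 1L]), end = max(spans[, 2L]), strand = strand,
       spans = spans)
}

#' Read a GenBank flat file
#'
#' Parses LOCUS, FEATURES (CDS entries) and ORIGIN of each record. CDS
#' coordinates are kept 1-based inclusive; the translation is taken from the
#' `/translation` qualifier or, when absent, computed with the bacterial
#' genetic code (translation table 11).
#'
#' @param path Path to a GenBank flat file (one or more LOCUS records).
#' @return A [genome_record()] for a single-record file, else a list of them.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  bounds <- grep("^LOCUS", lines)
  if (length(bounds) == 0L) stop("no LOCUS line found in ", path)
  ends <- c(bounds[-1L] - 1L, length(lines))
  records <- lapply(seq_along(bounds), function(k) {
    .parse_gb_record(lines[bounds[k]:ends[k]], path)
  })
  if (length(records) == 1L) records[[1L]] else records
}

.parse_gb_record <- function(lines, path) {
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  accession <- locus[2L]
  topology <- if (any(grepl("circular", lines[1L], ignore.case = TRUE)))
    "circular" else "linear"
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L)
    stop("record ", accession, " has no ORIGIN sequence block")
  seq_lines <- lines[(ori[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(feat_at)) {
    block <- lines[(feat_at[1L] + 1L):(ori[1L] - 1L)]
    # feature starts: 5-space indent + key
    starts <- grep("^ {5}\\S", block)
    n <- 0L
    rows <- list()
    for (i in seq_along(starts)) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1L] - 1L else length(block)
      key <- sub("^ {5}(\\S+).*", "\\1", block[from])
      if (key != "CDS") next
      body <- block[from:to]
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ {21}/", body)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
      loc <- paste(c(sub("^ {5}\\S+\\s+", "", body[1L]),
                     trimws(body[seq_len(loc_end)][-1L])), collapse = "")
      pl <- .parse_gb_location(loc)
      if (nrow(pl$spans) > 1L && pl$spans[1L, 1L] > pl$spans[nrow(pl$spans), 2L] &&
          topology == "linear")
        stop("CDS join() spans the origin of linear record ", accession)
      quals <- .parse_gb_qualifiers(body[-seq_len(loc_end)])
      n <- n + 1L
      locus_tag <- quals[["locus_tag"]] %||% sprintf("CDS_%04d", n)
      translation <- quals[["translation"]]
      if (is.null(translation)) {
        cds_seq <- substr(sequence, pl$start, pl$end)
        if (pl$strand == "-") cds_seq <- revcomp(cds_seq)
        translation <- .translate_cds(cds_seq)
      }
      rows[[n]] <- gene_feature(
        feature_id = locus_tag, locus_tag = locus_tag,
        start = pl$start, end = pl$end, strand = pl$strand,
        gene_name = quals[["gene"]] %||% NA_character_,
        product = quals[["product"]] %||% NA_character_,
        translation = translation, source = "genbank")
    }
    if (n) feats <- do.call(rbind, rows)
  }
  genome_record(accession, sequence, feats, topology)
}

.parse_gb_qualifiers <- function(lines) {
  quals <- list()
  cur_key <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) quals[[cur_key]] <<- gsub("\"", "", cur_val)
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      flush()
      eq <- regexpr("=", t, fixed = TRUE)
      if (eq > 0L) {
        cur_key <- substr(t, 2L, eq - 1L)
        cur_val <- substr(t, eq + 1L, nchar(t))
      } else {
        cur_key <- substr(t, 2L, nchar(t))
        cur_val <- "TRUE"
      }
    } else if (!is.null(cur_key)) {
      sep <- if (cur_key == "translation") "" else " "
      cur_val <- paste(cur_val, t, sep = sep)
    }
  }
  flush()
  quals
}

# Translate a CDS with the bacterial code; initiator codon reported as M.
.translate_cds <- function(cds_seq) {
  n <- nchar(cds_seq) - nchar(cds_seq) %% 3L
  if (n < 3L) return(NA_character_)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds_seq, 1L, n)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  aa <- sub("\\*$", "", aa)
  aa <- gsub("*", "X", aa, fixed = TRUE)  # internal stops (pseudogene/fixture)
  substr(aa, 1L, 1L) <- "M"
  aa
}

# --- FASTA --------------------------------------------------------------------

#' Read DNA from FASTA
#'
#' @param path FASTA file with one or more records.
#' @return A [genome_record()] (no features) for a single-record file, else a
#'   list of them in input order. Sequences are upper-cased; characters
#'   outside A,C,G,T,N are an error listing offending positions.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  records <- lapply(seq_along(ss), function(i) {
    nm <- strsplit(names(ss)[i], "\\s+")[[1L]][1L]
    genome_record(nm, as.character(ss[[i]]))
  })
  if (length(records) == 1L) records[[1L]] else records
}

# --- naive ORF calling --------------------------------------------------------

#' Naive ORF calling on a bare genome
#'
#' A deliberately simple open-reading-frame caller used when no annotation is
#' available: maximal ORFs on both strands with a start codon in ATG/GTG/TTG
#' and a stop in TAA/TAG/TGA, at least `min_aa` codons long (start and coding
#' codons, excluding the stop). Overlapping ORFs in the same strand and frame
#' share a stop; only the longest (5'-most start) is kept. Output features are
#' flagged `source = "naive_orf_caller"`.
#'
#' @param genome A [genome_record()] with no features.
#' @param min_aa Minimum ORF length in codons (excluding the stop).
#' @return Feature data frame (possibly empty).
#' @export
call_orfs <- function(genome, min_aa = 50L) {
  if (nrow(genome$features)) stop("call_orfs expects a genome without features")
  L <- nchar(genome$sequence)
  starts_set <- c("ATG", "GTG", "TTG")
  stops_set <- c("TAA", "TAG", "TGA")
  rows <- list()
  n <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    for (frame in 0:2) {
      codon_starts <- seq(frame + 1L, L - 2L, by = 3L)
      if (length(codon_starts) == 0L) next
      codons <- substring(s, codon_starts, codon_starts + 2L)
      is_stop <- codons %in% stops_set
      is_start <- codons %in% starts_set
      # segments between stops; first start in segment -> maximal ORF
      seg_start <- 1L
      bounds <- c(which(is_stop), length(codons) + 1L)
      for (b in bounds) {
        if (b > seg_start) {
          seg <- seg_start:(b - 1L)
          first_start <- seg[which(is_start[seg])[1L]]
          # require a stop codon (b <= length) for a complete ORF
          if (!is.na(first_start) && b <= length(codons)) {
            n_codons <- b - first_start
            if (n_codons >= min_aa) {
              orf_from <- codon_starts[first_start]
              orf_to <- codon_starts[b] + 2L  # include stop codon
              if (strand == "+") {
                start <- orf_from; end <- orf_to
              } else {
                start <- L - orf_to + 1L; end <- L - orf_from + 1L
              }
              n <- n + 1L
              cds <- substring(s, orf_from, orf_to)
              rows[[n]] <- gene_feature(
                feature_id = sprintf("orf_%04d", n),
                locus_tag = sprintf("orf_%04d", n),
                start = start, end = end, strand = strand,
                translation = .translate_cds(cds),
                source = "naive_orf_caller")
            }
          }
        }
        seg_start <- b + 1L
      }
    }
  }
  if (n == 0L) return(empty_features())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$feature_id <- sprintf("orf_%04d", seq_len(nrow(out)))
  out$locus_tag <- out$feature_id
  rownames(out) <- NULL
  out
}

# --- operons ------------------------------------------------------------------

#' Group genes into putative operons
#'
#' Consecutive same-strand genes whose intergenic gap is at most `max_gap_nt`
#' are merged into one operon; every gene belongs to exactly one operon. The
#' lead gene is the 5'-most member in transcription direction (first on `+`,
#' last forward-coordinate member on `-`).
#'
#' @param genome A [genome_record()] with features.
#' @param max_gap_nt Maximum intergenic gap within an operon (default 50).
#' @return List of operons, each a list with `members` (feature ids in
#'   transcription order), `lead_gene`, `strand`.
#' @export
group_operons <- function(genome, max_gap_nt = 50L) {
  f <- genome$features
  if (nrow(f) == 0L) stop("genome has no features to group")
  f <- f[order(f$start), , drop = FALSE]
  grp <- integer(nrow(f))
  g <- 1L
  grp[1L] <- g
  for (i in seq_len(nrow(f))[-1L]) {
    gap <- f$start[i] - f$end[i - 1L] - 1L
    if (f$strand[i] != f$strand[i - 1L] || gap > max_gap_nt) g <- g + 1L
    grp[i] <- g
  }
  lapply(split(seq_len(nrow(f)), grp), function(idx) {
    strand <- f$strand[idx[1L]]
    ids <- f$feature_id[idx]                  # in forward coordinate order
    if (strand == "-") ids <- rev(ids)        # transcription order
    list(members = ids, lead_gene = ids[1L], strand = strand)
  })
}

# --- upstream extraction ------------------------------------------------------

#' Extract the upstream intergenic region of a gene or operon
#'
#' The region runs from up to `max_upstream_nt` upstream of the lead gene's
#' start (truncated at the nearest other feature boundary, regardless of its
#' strand) through `gene_prefix_nt` bases into the gene. Minus-strand targets
#' are reverse-complemented so the returned sequence reads 5'->3' toward the
#' gene start; circular genomes wrap across the origin.
#'
#' @param genome A [genome_record()].
#' @param target An operon (from [group_operons()]) or a feature id.
#' @param max_upstream_nt Maximum upstream flank (default 300).
#' @param gene_prefix_nt Gene-internal bases appended (default 20).
#' @return An `intergenic_region`: list with `sequence` (gene-oriented),
#'   `anchor_gene`, `operon_members`, `upstream_flank_len`, `gene_prefix_len`,
#'   `genome_start`, `genome_end` (forward coordinates of the slice) and
#'   `strand`.
#' @export
extract_upstream <- function(genome, target, max_upstream_nt = 300L,
                             gene_prefix_nt = 20L) {
  f <- genome$features
  if (is.character(target)) {
    target <- list(members = target, lead_gene = target,
                   strand = f$strand[match(target, f$feature_id)])
  }
  lead <- match(target$lead_gene, f$feature_id)
  if (is.na(lead)) stop("lead gene ", target$lead_gene, " not found in genome")
  L <- nchar(genome$sequence)
  strand <- f$strand[lead]
  gene_prefix_nt <- min(gene_prefix_nt, f$end[lead] - f$start[lead] + 1L)
  own <- f$feature_id %in% target$members

  if (strand == "+") {
    anchor <- f$start[lead]
    # nearest feature boundary upstream (any strand, excluding operon members)
    prev_ends <- f$end[!own & f$end < anchor]
    if (genome$topology == "circular") {
      room <- if (length(prev_ends)) anchor - max(prev_ends) - 1L else {
        wrap_ends <- f$end[!own]   # features anywhere, measured around origin
        if (length(wrap_ends)) anchor - 1L + (L - max(wrap_ends)) else L
      }
    } else {
      room <- if (length(prev_ends)) anchor - max(prev_ends) - 1L else anchor - 1L
    }
    flank <- max(0L, min(max_upstream_nt, room))
    if (flank == 0L && gene_prefix_nt == 0L)
      stop("empty upstream region for gene ", target$lead_gene)
    gstart <- anchor - flank
    gend <- anchor + gene_prefix_nt - 1L
    if (gstart >= 1L) {
      seq <- substr(genome$sequence, gstart, gend)
    } else {
      # circular wrap across the origin
      seq <- paste0(substr(genome$sequence, L + gstart, L),
                    substr(genome$sequence, 1L, gend))
      gstart <- L + gstart
    }
  } else {
    anchor <- f$end[lead]
    next_starts <- f$start[!own & f$start > anchor]
    if (genome$topology == "circular") {
      room <- if (length(next_starts)) min(next_starts) - anchor - 1L else {
        wrap_starts <- f$start[!own]
        if (length(wrap_starts)) (L - anchor) + min(wrap_starts) - 1L else L
      }
    } else {
      room <- if (length(next_starts)) min(next_starts) - anchor - 1L else L - anchor
    }
    flank <- max(0L, min(max_upstream_nt, room))
    if (flank == 0L && gene_prefix_nt == 0L)
      stop("empty upstream region for gene ", target$lead_gene)
    gstart <- anchor - gene_prefix_nt + 1L
    gend <- anchor + flank
    if (gend <= L) {
      seq <- substr(genome$sequence, gstart, gend)
    } else {
      seq <- paste0(substr(genome$sequence, gstart, L),
                    substr(genome$sequence, 1L, gend - L))
      gend <- gend - L
    }
    seq <- revcomp(seq)
  }
  structure(list(sequence = seq, anchor_gene = target$lead_gene,
                 operon_members = target$members,
                 upstream_flank_len = flank, gene_prefix_len = gene_prefix_nt,
                 genome_start = gstart, genome_end = gend, strand = strand),
            class = "intergenic_region")
}

#' Map a region-local interval to forward genome coordinates
#'
#' @param region An `intergenic_region` from [extract_upstream()].
#' @param local_start,local_end 1-based inclusive positions in
#'   `region$sequence`.
#' @return List with `start`, `end` (forward coordinates) and `strand`.
#' @export
region_to_genome <- function(region, local_start, local_end) {
  n <- nchar(region$sequence)
  stopifnot(local_start >= 1L, local_end <= n, local_start <= local_end)
  if (region$strand == "+") {
    list(start = region$genome_start + local_start - 1L,
         end = region$genome_start + local_end - 1L, strand = "+")
  } else {
    list(start = region$genome_end - local_end + 1L,
         end = region$genome_end - local_start + 1L, strand = "-")
  }
}

#' @export
print.intergenic_region <- function(x, ...) {
  cat(sprintf("intergenic_region of %s (%s)  %d nt = %d upstream + %d gene prefix\n",
              x$anchor_gene, x$strand, nchar(x$sequence),
              x$upstream_flank_len, x$gene_prefix_len))
  invisible(x)
}

# --- GFF3 ---------------------------------------------------------------------

.gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write annotations as GFF3
#'
#' @param annotations Data frame with columns `seqid`, `source`, `type`,
#'   `start`, `end` (1-based inclusive), `score`, `strand` and `attributes`
#'   (pre-formatted `key=value;...` strings, or NA). P-values placed in
#'   attributes should be formatted with [format_pvalue()].
#' @param path Output path.
#' @param genome_length Optional replicon length for the
#'   `##sequence-region` pragma and coordinate validation.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotations, path, genome_length = NULL) {
  a <- as.data.frame(annotations, stringsAsFactors = FALSE)
  header <- "##gff-version 3"
  if (!is.null(genome_length) && nrow(a)) {
    header <- c(header, sprintf("##sequence-region %s 1 %d",
                                unique(a$seqid)[1L], genome_length))
    if (any(a$start < 1L) || any(a$end > genome_length))
      stop("annotation coordinates outside the genome")
  }
  lines <- header
  if (nrow(a)) {
    score <- ifelse(is.na(a$score), ".", formatC(a$score, format = "g", digits = 6))
    attrs <- ifelse(is.na(a$attributes) | a$attributes == "", ".", a$attributes)
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                              a$seqid, a$source, a$type, as.integer(a$start),
                              as.integer(a$end), score, a$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff()]
#'
#' @param path GFF3 file path.
#' @return Data frame with the [write_gff()] columns.
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = numeric(), strand = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(seqid = parts[, 1L], source = parts[, 2L], type = parts[, 3L],
             start = as.integer(parts[, 4L]), end = as.integer(parts[, 5L]),
             score = suppressWarnings(as.numeric(ifelse(parts[, 6L] == ".",
                                                        NA, parts[, 6L]))),
             strand = parts[, 7L], attributes = parts[, 9L],
             stringsAsFactors = FALSE)
}

#' Format a p-value for GFF attributes
#'
#' @param p Numeric p-value.
#' @return String like `"1.0e-06"`.
#' @export
format_pvalue <- function(p) sprintf("%.1e", p)
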