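# Reading and writing of FASTA / GFF3 / taxonomy inputs.
#
# All internal coordinates are 0-based half-open [start, end); GFF3's 1-based
# inclusive spans are converted on read so that every downstream offset
# computation uses a single convention.

#' Read a (possibly gzip-compressed) FASTA file
#'
#' Reads a multi-record nucleotide FASTA file, plain or gzip-compressed, into a
#' list of sequence records. The accession is the first whitespace-delimited
#' token of each header; the remainder of the header is kept as the
#' description. A record is flagged as a plasmid when its description contains
#' the substring `"plasmid"` (case-insensitive), matching common NCBI header
#' practice.
#'
#' @param path Path to a FASTA file (`.fa`, `.fasta`, optionally `.gz`).
#' @return A list of `sequence_record` objects, in file order. Each record is a
#'   list with elements `accession`, `description`, `residues` (upper-case
#'   nucleotide string, IUPAC codes retained) and `is_plasmid`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test plasmid pX", "ACGT"), fa)
#' recs <- read_fasta(fa)
#' recs[[1]]$is_plasmid
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  set <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- names(set)[Biostrings::width(set) == 0L][1]
    stop("zero-length sequence in FASTA record: ", bad)
  }
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    accession <- sub("\\s.*$", "", header)
    description <- sub("^\\S+\\s*", "", header)
    if (!nzchar(accession)) {
      stop("FASTA record ", i, " has an empty header")
    }
    sequence_record(
      accession = accession,
      description = description,
      residues = toupper(as.character(set[[i]])),
      is_plasmid = grepl("plasmid", description, ignore.case = TRUE)
    )
  })
}

#' Construct a sequence record
#'
#' @param accession Non-empty identifier string.
#' @param description Free-text header remainder (may be empty).
#' @param residues Upper-case nucleotide string.
#' @param is_plasmid Logical plasmid flag.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(accession, description = "", residues,
                            is_plasmid = FALSE) {
  stopifnot(nzchar(accession), nchar(residues) > 0L)
  structure(
    list(
      accession = accession,
      description = description,
      residues = toupper(residues),
      is_plasmid = isTRUE(is_plasmid)
    ),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf(
    "<sequence_record> %s (%d nt)%s\n", x$accession, nchar(x$residues),
    if (x$is_plasmid) " [plasmid]" else ""
  ))
  invisible(x)
}

#' Write sequence records to a FASTA file
#'
#' @param records List of `sequence_record` objects.
#' @param path Output path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$accession, r$description) else r$accession
  }, "")
  Biostrings::writeXStringSet(seqs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read protein-coding gene annotations from a GFF3 file
#'
#' Parses a GFF3 annotation file (plain or gzip-compressed) and retains
#' protein-coding gene features only. `CDS` features are the primary carrier of
#' codon phase and are always retained; if (and only if) a file carries no
#' `CDS` features at all, `gene` features with a
#' `gene_biotype=protein_coding` attribute are accepted as a fallback, so that
#' minimal annotation files remain usable without double-counting genes in
#' fully annotated ones.
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to
#' 0-based half-open; strand is encoded as `+1` / `-1`. The `Name=` attribute
#' (or `gene=` when `Name` is absent) is captured as the gene name.
#'
#' @param path Path to a GFF3 file (optionally `.gz`).
#' @return A data.frame with columns `seq_id`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (+1/-1), `feature_type`, `name`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read GFF3 file: ", path)
  }
  con <- gzfile(path, "rt") # transparently reads plain text too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  # stop at an embedded ##FASTA section, if any
  fasta_at <- match("##FASTA", lines)
  if (!is.na(fasta_at)) body <- body[body < fasta_at]
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfields != 9L)) {
    bad <- body[which(nfields != 9L)[1]]
    stop("GFF3 feature line ", bad, " has ", nfields[which(nfields != 9L)[1]],
         " columns, expected 9")
  }
  if (length(body) == 0L) {
    return(empty_gene_table())
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  keep <- g$type == "CDS"
  if (!any(keep) && "gene_biotype" %in% names(g)) {
    keep <- g$type == "gene" & !is.na(g$gene_biotype) &
      g$gene_biotype == "protein_coding"
  }
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(empty_gene_table())
  }
  strand <- as.character(g$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("unstranded protein-coding feature in ", path)
  }
  name <- rep(NA_character_, nrow(g))
  if ("Name" %in% names(g)) name <- as.character(g$Name)
  if ("gene" %in% names(g)) {
    gn <- as.character(g$gene)
    name[is.na(name)] <- gn[is.na(name)]
  }
  name[is.na(name)] <- ""
  out <- data.frame(
    seq_id = as.character(g$seqid),
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    strand = ifelse(strand == "+", 1L, -1L),
    feature_type = as.character(g$type),
    name = name,
    stringsAsFactors = FALSE
  )
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' An empty gene annotation table
#'
#' The zero-row counterpart of [read_gff3()]'s return value, for
#' annotation-free scans.
#'
#' @return A zero-row gene table with the standard columns.
#' @export
empty_gene_table <- function() {
  data.frame(
    seq_id = character(), start = integer(), end = integer(),
    strand = integer(), feature_type = character(), name = character(),
    stringsAsFactors = FALSE
  )
}

#' Write gene annotations to a GFF3 file
#'
#' Inverse of [read_gff3()] for the retained fields: emits one `CDS` line per
#' gene, converting internal 0-based half-open coordinates back to GFF3's
#' 1-based inclusive convention.
#'
#' @param genes Gene table as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  if (nrow(genes) > 0L) {
    attrs <- sprintf("ID=cds%d", seq_len(nrow(genes)))
    named <- nzchar(genes$name)
    attrs[named] <- paste0(attrs[named], ";Name=", genes$name[named])
    lines <- c(lines, sprintf(
      "%s\tskewfit\tCDS\t%d\t%d\t.\t%s\t0\t%s",
      genes$seq_id, genes$start + 1L, genes$end,
      ifelse(genes$strand > 0L, "+", "-"), attrs
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Drop records below a minimum length
#'
#' Short chromosomes and plasmids are too noisy to model faithfully; the
#' default threshold of 100 kb removes them while preserving input order.
#'
#' @param records List of `sequence_record` objects.
#' @param threshold Minimum length in nucleotides (default 100000).
#' @return The records whose residue length is `>= threshold`, order preserved.
#' @export
filter_min_length <- function(records, threshold = 100000L) {
  stopifnot(threshold > 0L)
  records[vapply(records, function(r) nchar(r$residues), 0L) >= threshold]
}

#' Load an accession-to-taxonomy mapping
#'
#' Reads a tab-separated file with six columns: accession followed by five
#' taxonomy strings (`realm1`..`realm5`). Malformed lines are skipped with a
#' warning; on duplicate accessions the last entry wins (also warned about).
#'
#' @param path Path to the mapping file.
#' @return An object of class `taxonomy_map`; query it with
#'   [taxonomy_lookup()].
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read taxonomy file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 6L
  if (any(!ok)) {
    warning(sum(!ok), " malformed taxonomy line(s) skipped")
  }
  parts <- parts[ok]
  acc <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(acc)) {
    warning(sum(duplicated(acc)), " duplicate taxonomy accession(s); last entry wins")
  }
  m <- do.call(rbind, lapply(parts, function(p) p[2:6]))
  map <- new.env(parent = emptyenv())
  for (i in seq_along(acc)) assign(acc[i], m[i, ], envir = map) # last wins
  structure(list(map = map), class = "taxonomy_map")
}

#' Look up the taxonomy of an accession
#'
#' @param taxonomy A `taxonomy_map` from [load_taxonomy()], or `NULL`.
#' @param accession Accession string.
#' @param unknown Placeholder used for missing accessions (and when `taxonomy`
#'   is `NULL`).
#' @return Character vector of five taxonomy strings.
#' @export
taxonomy_lookup <- function(taxonomy, accession, unknown = "unknown") {
  if (is.null(taxonomy) ||
      !exists(accession, envir = taxonomy$map, inherits = FALSE)) {
    return(rep(unknown, 5L))
  }
  get(accession, envir = taxonomy$map, inherits = FALSE)
}
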