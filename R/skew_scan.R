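# Single-pass cumulative skew scanner.
#
# The scanner traverses the reference strand from beginning to end and keeps
# running totals for:
#   * cumulative GC skew (G - C) and TA skew (T - A), genome-wide;
#   * the same two skews split by codon position (0/1/2) inside protein-coding
#     genes and a non-coding remainder bucket, so that the four buckets always
#     sum to the genome-wide total;
#   * a gene strand-bias counter (+1 per positive-sense genic nucleotide, -1
#     per negative-sense, 0 outside genes);
#   * a non-genic nucleotide counter and plain A/C/G/T counts.
# Totals are snapshotted every `interval` nucleotides (default 4096) and once
# at the sequence end. Ambiguity codes advance the position but touch no
# counter.

BASE_A <- utf8ToInt("A")
BASE_C <- utf8ToInt("C")
BASE_G <- utf8ToInt("G")
BASE_T <- utf8ToInt("T")

#' Cumulative two-base skew of a sequence
#'
#' Returns the running total of `count(plus_base) - count(minus_base)` after
#' each position of the sequence. For example, the sequence `"GGGCCC"` has a
#' cumulative GC skew trajectory of 1, 2, 3, 2, 1, 0: three rises followed by
#' three falls, ending at zero because G and C occur equally often. Characters
#' other than the two counted bases leave the total unchanged.
#'
#' @param residues Non-empty nucleotide string.
#' @param plus_base Base that increments the total (default `"G"`).
#' @param minus_base Base that decrements the total (default `"C"`).
#' @return Integer vector of running totals, one per position.
#' @examples
#' cumulative_skew("GGGCCC") # 1 2 3 2 1 0
#' @export
cumulative_skew <- function(residues, plus_base = "G", minus_base = "C") {
  stopifnot(nchar(residues) > 0L)
  ints <- utf8ToInt(toupper(residues))
  cumsum((ints == utf8ToInt(toupper(plus_base))) -
           (ints == utf8ToInt(toupper(minus_base))))
}

#' Windowed GC-style skew
#'
#' Computes `(G - C) / (G + C)` over consecutive non-overlapping windows of
#' `window` bases. A window containing neither counted base yields 0 rather
#' than NaN, keeping the result a total function; a trailing partial window is
#' dropped. This windowed form is provided for illustration and comparison --
#' the scanning pipeline itself uses cumulative skew exclusively, which
#' sidesteps the window-size sensitivity of this statistic.
#'
#' @param residues Nucleotide string.
#' @param window Window size `N >= 1`.
#' @param plus_base,minus_base The two counted bases (defaults G and C).
#' @return Numeric vector with one skew value per complete window.
#' @examples
#' windowed_skew("GGGCCC", 6) # 0
#' @export
windowed_skew <- function(residues, window, plus_base = "G", minus_base = "C") {
  if (window < 1L) stop("window size must be >= 1")
  ints <- utf8ToInt(toupper(residues))
  n_win <- length(ints) %/% window
  if (n_win == 0L) return(numeric(0))
  ints <- ints[seq_len(n_win * window)]
  grp <- rep(seq_len(n_win), each = window)
  plus <- tapply(ints == utf8ToInt(toupper(plus_base)), grp, sum)
  minus <- tapply(ints == utf8ToInt(toupper(minus_base)), grp, sum)
  tot <- plus + minus
  as.numeric(ifelse(tot == 0, 0, (plus - minus) / tot))
}

#' Codon position of an offset within a CDS
#'
#' Classifies a 0-based offset within a coding sequence into codon position
#' 0, 1 or 2, counted from the gene's own 5' end: on the plus strand this is
#' `offset %% 3`; on the minus strand the gene is read from its right edge, so
#' the phase is `(cds_length - 1 - offset) %% 3`.
#'
#' @param offset_in_cds 0-based offset, `0 <= offset < cds_length`.
#' @param strand `+1` or `-1`.
#' @param cds_length CDS length in nucleotides (multiple of 3).
#' @return Integer codon position in `{0, 1, 2}`.
#' @export
codon_position_of <- function(offset_in_cds, strand, cds_length) {
  stopifnot(all(offset_in_cds >= 0L), all(offset_in_cds < cds_length),
            strand %in% c(1L, -1L))
  if (strand > 0L) offset_in_cds %% 3L else (cds_length - 1L - offset_in_cds) %% 3L
}

validate_genes <- function(record, genes) {
  if (nrow(genes) == 0L) return(invisible(genes))
  len <- nchar(record$residues)
  if (any(genes$start < 0L | genes$end > len | genes$start >= genes$end)) {
    stop("gene annotation out of bounds for ", record$accession)
  }
  invisible(genes)
}

#' Scan a chromosome, emitting all cumulative counters at fixed intervals
#'
#' Performs the single pass over the sequence described in the package
#' overview, snapshotting every counter at positions `interval`,
#' `2*interval`, ... plus a final checkpoint at the sequence end. Codon
#' position buckets are assigned per gene from the gene's own 5' end; a
#' nucleotide covered by several genes is classified by the first gene in
#' coordinate order (so that the codon-position buckets plus the non-coding
#' bucket always partition the total skew), while the strand-bias counter
#' receives the sum of contributions of all covering genes. Genes whose length
#' is not a multiple of 3 are excluded from codon-position accounting with a
#' warning, but still count as genic for the strand-bias and non-genic
#' counters.
#'
#' @param record A `sequence_record`.
#' @param genes Gene table for this record (as from [read_gff3()]); rows with
#'   a different `seq_id` are ignored.
#' @param interval Checkpoint spacing in nucleotides (default 4096).
#' @return A `scan_profile` object: a list with `accession`, `length`,
#'   `interval` and a `checkpoints` data.frame with columns `abspos`,
#'   `relpos`, `gcskew`, `taskew`, `gcskew0..2`, `taskew0..2`, `gcskewNG`,
#'   `taskewNG`, `pospos`, `ngcount`, `acount`, `ccount`, `gcount`, `tcount`.
#' @export
scan_chromosome <- function(record, genes = empty_gene_table(),
                            interval = 4096L) {
  stopifnot(interval >= 1L)
  genes <- genes[genes$seq_id == record$accession, , drop = FALSE]
  validate_genes(record, genes)
  ints <- utf8ToInt(record$residues)
  len <- length(ints)

  # per-position skew contributions
  is_a <- ints == BASE_A
  is_c <- ints == BASE_C
  is_g <- ints == BASE_G
  is_t <- ints == BASE_T
  d_gc <- is_g - is_c
  d_ta <- is_t - is_a

  # gene-derived per-position classifications
  cls <- rep.int(3L, len)          # 0/1/2 codon position, 3 = unclassified
  assigned <- logical(len)
  strand_sum <- integer(len)
  genic <- logical(len)
  if (nrow(genes) > 0L) {
    genes <- genes[order(genes$start), , drop = FALSE]
    skipped <- 0L
    for (i in seq_len(nrow(genes))) {
      idx <- (genes$start[i] + 1L):genes$end[i]
      glen <- genes$end[i] - genes$start[i]
      strand_sum[idx] <- strand_sum[idx] + genes$strand[i]
      genic[idx] <- TRUE
      if (glen %% 3L != 0L) {
        skipped <- skipped + 1L
        next
      }
      ph <- codon_position_of(0:(glen - 1L), genes$strand[i], glen)
      sel <- !assigned[idx]
      cls[idx[sel]] <- ph[sel]
      assigned[idx] <- TRUE
    }
    if (skipped > 0L) {
      warning(skipped, " gene(s) with length not a multiple of 3 excluded ",
              "from codon-position accounting (", record$accession, ")")
    }
  }

  cp <- if (len < interval) integer(0) else seq.int(interval, len, by = interval)
  if (length(cp) == 0L || cp[length(cp)] != len) cp <- c(cp, len)

  pick <- function(x) cumsum(x)[cp]
  checkpoints <- data.frame(
    abspos = cp,
    relpos = cp / len,
    gcskew = pick(d_gc),
    taskew = pick(d_ta),
    gcskew0 = pick(d_gc * (cls == 0L)),
    gcskew1 = pick(d_gc * (cls == 1L)),
    gcskew2 = pick(d_gc * (cls == 2L)),
    taskew0 = pick(d_ta * (cls == 0L)),
    taskew1 = pick(d_ta * (cls == 1L)),
    taskew2 = pick(d_ta * (cls == 2L)),
    gcskewNG = pick(d_gc * (cls == 3L)),
    taskewNG = pick(d_ta * (cls == 3L)),
    pospos = pick(strand_sum),
    ngcount = pick(!genic),
    acount = pick(is_a),
    ccount = pick(is_c),
    gcount = pick(is_g),
    tcount = pick(is_t)
  )
  structure(
    list(accession = record$accession, length = len, interval = interval,
         checkpoints = checkpoints),
    class = "scan_profile"
  )
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf("<scan_profile> %s: %d nt, %d checkpoints every %d nt\n",
              x$accession, x$length, nrow(x$checkpoints), x$interval))
  invisible(x)
}

#' Extract one skew track from a scan profile
#'
#' @param profile A `scan_profile`.
#' @param skew One of the checkpoint column names, e.g. `"gcskew"`,
#'   `"taskew0"`, `"pospos"`.
#' @return A `skew_track`: list with `interval`, `positions`, `values`.
#' @export
profile_track <- function(profile, skew = "gcskew") {
  stopifnot(inherits(profile, "scan_profile"),
            skew %in% names(profile$checkpoints))
  skew_track(positions = profile$checkpoints$abspos,
             values = as.numeric(profile$checkpoints[[skew]]),
             interval = profile$interval)
}

#' Construct a skew track
#'
#' @param positions Strictly increasing integer offsets.
#' @param values Cumulative totals, one per position.
#' @param interval Nominal checkpoint spacing.
#' @return An object of class `skew_track`.
#' @export
skew_track <- function(positions, values, interval = 4096L) {
  stopifnot(length(positions) == length(values),
            !is.unsorted(positions, strictly = TRUE))
  structure(list(interval = interval, positions = as.numeric(positions),
                 values = as.numeric(values)),
            class = "skew_track")
}

revcomp <- function(s) {
  chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
         "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn",
         paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
}

#' Tally start and stop codons over protein-coding genes
#'
#' For each gene the first codon (after reverse-complementing minus-strand
#' genes, so always in reading direction) is classified as ATG/GTG/TTG/other
#' and the last codon as TAG/TAA/TGA/other. Anomalies land in the `XXX`
#' buckets, so the start buckets and the stop buckets each always sum to the
#' number of genes processed.
#'
#' @param record A `sequence_record`.
#' @param genes Gene table for this record.
#' @return A list with `protgenecount`, `startATG`, `startGTG`, `startTTG`,
#'   `startXXX`, `stopTAG`, `stopTAA`, `stopTGA`, `stopXXX`.
#' @export
tally_codons <- function(record, genes) {
  genes <- genes[genes$seq_id == record$accession, , drop = FALSE]
  validate_genes(record, genes)
  tal <- list(protgenecount = nrow(genes),
              startATG = 0L, startGTG = 0L, startTTG = 0L, startXXX = 0L,
              stopTAG = 0L, stopTAA = 0L, stopTGA = 0L, stopXXX = 0L)
  for (i in seq_len(nrow(genes))) {
    sub <- substr(record$residues, genes$start[i] + 1L, genes$end[i])
    if (genes$strand[i] < 0L) sub <- revcomp(sub)
    first <- substr(sub, 1L, 3L)
    last <- substr(sub, nchar(sub) - 2L, nchar(sub))
    skey <- switch(first, ATG = "startATG", GTG = "startGTG",
                   TTG = "startTTG", "startXXX")
    ekey <- switch(last, TAG = "stopTAG", TAA = "stopTAA",
                   TGA = "stopTGA", "stopXXX")
    tal[[skey]] <- tal[[skey]] + 1L
    tal[[ekey]] <- tal[[ekey]] + 1L
  }
  tal
}

#' Locate the DnaA replication-initiator gene
#'
#' DnaA is typically found near the origin of replication, so its position is
#' an annotation-based sanity check on the fitted origin shift. Matches the
#' gene name `"dnaA"` case-insensitively.
#'
#' @param genes Gene table.
#' @return 0-based start offset of the first matching annotation in coordinate
#'   order, or `-1` when absent.
#' @export
find_dnaA <- function(genes) {
  hit <- which(tolower(genes$name) == "dnaa")
  if (length(hit) == 0L) return(-1L)
  min(genes$start[hit])
}

#' Per-strand coding nucleotide composition
#'
#' Computes the base composition of coding nucleotides read on each gene's
#' sense strand, overall and split by replication strand. A gene is assigned
#' to the leading strand when it is positive-sense on the fitted leading arc
#' (the arc of fraction `div` starting at fraction `shift`) or negative-sense
#' on the lagging arc; genes are classified by their midpoint. The derived
#' `ggcfrac` (G share of coding G+C) and `ttafrac` (T share of coding A+T)
#' quantify codon bias, which multiplied by strand bias predicts gene-driven
#' skew.
#'
#' @param record A `sequence_record`.
#' @param genes Gene table for this record.
#' @param div Leading-strand fraction from the GC fit.
#' @param shift Origin shift fraction from the GC fit.
#' @return A list of fractions: `afrac..tfrac`, `leadafrac..leadtfrac`,
#'   `lagafrac..lagtfrac`, `ggcfrac`, `cgcfrac`, `atafrac`, `ttafrac`.
#' @export
coding_composition <- function(record, genes, div = 0.5, shift = 0) {
  genes <- genes[genes$seq_id == record$accession, , drop = FALSE]
  validate_genes(record, genes)
  len <- nchar(record$residues)
  tot <- lead <- lag <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_len(nrow(genes))) {
    sub <- substr(record$residues, genes$start[i] + 1L, genes$end[i])
    ii <- utf8ToInt(sub)
    cnt <- c(A = sum(ii == BASE_A), C = sum(ii == BASE_C),
             G = sum(ii == BASE_G), T = sum(ii == BASE_T))
    if (genes$strand[i] < 0L) cnt <- cnt[c("T", "G", "C", "A")]
    names(cnt) <- c("A", "C", "G", "T")
    mid_frac <- ((genes$start[i] + genes$end[i]) / 2 / len - shift) %% 1
    on_arc1 <- mid_frac < div
    is_leading <- (on_arc1 && genes$strand[i] > 0L) ||
      (!on_arc1 && genes$strand[i] < 0L)
    tot <- tot + cnt
    if (is_leading) lead <- lead + cnt else lag <- lag + cnt
  }
  frac <- function(x) if (sum(x) == 0) rep(0, 4) else x / sum(x)
  ft <- frac(tot); fl <- frac(lead); fg <- frac(lag)
  gc <- tot[["G"]] + tot[["C"]]
  at <- tot[["A"]] + tot[["T"]]
  list(
    afrac = ft[[1]], cfrac = ft[[2]], gfrac = ft[[3]], tfrac = ft[[4]],
    leadafrac = fl[[1]], leadcfrac = fl[[2]], leadgfrac = fl[[3]],
    leadtfrac = fl[[4]],
    lagafrac = fg[[1]], lagcfrac = fg[[2]], laggfrac = fg[[3]],
    lagtfrac = fg[[4]],
    ggcfrac = if (gc == 0) 0.5 else tot[["G"]] / gc,
    cgcfrac = if (gc == 0) 0.5 else tot[["C"]] / gc,
    atafrac = if (at == 0) 0.5 else tot[["A"]] / at,
    ttafrac = if (at == 0) 0.5 else tot[["T"]] / at
  )
}
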