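# Synthetic genomes with planted replichore structure.
#
# Two emission modes:
#   * "none" (deterministic): every position is produced by four per-base
#     floor schedules with per-position rates P(G) = 1/4 + r_gc/2,
#     P(C) = 1/4 - r_gc/2, P(T) = 1/4 + r_ta/2, P(A) = 1/4 - r_ta/2 (r_* are
#     the signed planted rates of the current arc). Base b fires at position k
#     when floor(cumsum(P_b)) increments; the fired events, taken in scheduled
#     order, ARE the sequence. Wherever n * P_b is integral for all bases
#     (e.g. every 1000 nt for the worked rates) the realized excess counts are
#     exact: at rate 0.046 the first 1000 leading-strand nucleotides contain
#     exactly 46 excess G.
#   * "binomial": seeded per-position multinomial draws with the same
#     probabilities, giving realistic counting noise.
# Genes are laid down as non-overlapping CDS annotations that avoid the two
# replichore breakpoints; only their start codon (ATG) and stop codon (TAA)
# are stamped into the sequence. In deterministic mode the small skew damage
# done by stamping is repaired by flipping a matching number of bases
# elsewhere in the same arc, so planted per-arc excess totals stay exact.

#' Specification of a synthetic genome
#'
#' Defaults describe a realistic mid-size bacterial chromosome: 2^20 nt,
#' leading-strand G excess of 46 per 1000 nt (a typical strongly skewed
#' genome), a concordant TA skew about half that size, a slightly asymmetric
#' replichore split, ~85% coding density and a moderate leading-strand gene
#' preference.
#'
#' @param length Genome length in nucleotides (>= 8192).
#' @param gc_alpha1,gc_alpha2 Planted leading/lagging G-excess rates.
#' @param ta_alpha1,ta_alpha2 Planted T-excess rates; negative values give
#'   Firmicute-style skews discordant with GC.
#' @param div Leading-strand fraction in (0, 1).
#' @param shift Origin offset fraction in [0, 1).
#' @param gene_density Fraction of the genome covered by CDS, in [0, 0.95].
#' @param leading_strand_gene_fraction Probability that a gene is
#'   leading-strand oriented.
#' @param codon_g_fraction G share of coding G+C nucleotides on the sense
#'   strand; 0.5 (default) leaves the arc emission untouched, other values
#'   re-draw gene-body G/C identities and thereby plant gene-driven skew.
#' @param noise `"none"` (deterministic) or `"binomial"`.
#' @param seed Integer seed for gene placement and stochastic emission.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(length = 1048576L,
                           gc_alpha1 = 0.046, gc_alpha2 = 0.046,
                           ta_alpha1 = 0.025, ta_alpha2 = 0.025,
                           div = 0.557, shift = 0,
                           gene_density = 0.85,
                           leading_strand_gene_fraction = 0.7,
                           codon_g_fraction = 0.5,
                           noise = c("none", "binomial"),
                           seed = 1L) {
  noise <- match.arg(noise)
  rates <- c(gc_alpha1, gc_alpha2, ta_alpha1, ta_alpha2)
  if (length < 2L * 4096L) stop("length must be at least 8192")
  if (any(abs(rates) >= 0.5)) stop("skew rates must lie in (-0.5, 0.5)")
  if (div <= 0 || div >= 1) stop("div must lie strictly inside (0, 1)")
  if (shift < 0 || shift >= 1) stop("shift must lie in [0, 1)")
  if (gene_density < 0 || gene_density > 0.95) {
    stop("gene_density must lie in [0, 0.95] to be placeable")
  }
  if (leading_strand_gene_fraction < 0 || leading_strand_gene_fraction > 1 ||
      codon_g_fraction < 0 || codon_g_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  structure(
    list(length = as.integer(length),
         gc_alpha1 = gc_alpha1, gc_alpha2 = gc_alpha2,
         ta_alpha1 = ta_alpha1, ta_alpha2 = ta_alpha2,
         div = div, shift = shift, gene_density = gene_density,
         leading_strand_gene_fraction = leading_strand_gene_fraction,
         codon_g_fraction = codon_g_fraction, noise = noise,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Sample a skew track directly from the replichore model
#'
#' Evaluates the model at the 4096-nt checkpoint grid (plus the final
#' position) and adds seeded Gaussian noise; the quick way to exercise the
#' fitting machinery without building a whole genome.
#'
#' @param params A `fit_params` with the planted truth.
#' @param length Genome length in nucleotides.
#' @param noise_sd Standard deviation of additive noise (0 = exact model).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param interval Checkpoint spacing.
#' @return A `skew_track`.
#' @export
simulate_track <- function(params, length, noise_sd = 0, seed = 1L,
                           interval = 4096L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  pos <- seq.int(interval, length, by = interval)
  if (pos[base::length(pos)] != length) pos <- c(pos, length)
  values <- model_eval(params, length, pos)
  if (noise_sd > 0) {
    values <- values + withr::with_seed(seed, stats::rnorm(base::length(pos),
                                                           0, noise_sd))
  }
  skew_track(positions = pos, values = values, interval = interval)
}

# signed per-position rates for both channels given arc membership
arc_rates <- function(spec) {
  len <- spec$length
  p <- seq_len(len) - 1L
  frac <- ((p / len) - spec$shift) %% 1
  leading <- frac < spec$div
  list(
    leading = leading,
    gc = ifelse(leading, spec$gc_alpha1, -spec$gc_alpha2),
    ta = ifelse(leading, spec$ta_alpha1, -spec$ta_alpha2)
  )
}

# deterministic emission: merge the four per-base floor schedules
emit_deterministic <- function(p_a, p_c, p_g, p_t, len) {
  fires <- function(p) which(diff(c(0, floor(cumsum(p) + 1e-9))) >= 1L)
  fa <- fires(p_a); fc <- fires(p_c); fg <- fires(p_g); ft <- fires(p_t)
  ev_pos <- c(fa, fc, fg, ft)
  ev_base <- rep(c(BASE_A, BASE_C, BASE_G, BASE_T),
                 times = c(length(fa), length(fc), length(fg), length(ft)))
  ord <- order(ev_pos, ev_base)
  codes <- ev_base[ord]
  if (length(codes) >= len) {
    codes[seq_len(len)]
  } else {
    # schedules can run up to 4 events short of len; pad neutrally
    c(codes, rep(c(BASE_A, BASE_T, BASE_G, BASE_C),
                 length.out = len - length(codes)))
  }
}

emit_stochastic <- function(p_a, p_c, p_g, p_t, len) {
  u <- stats::runif(len)
  cum1 <- p_a
  cum2 <- p_a + p_c
  cum3 <- cum2 + p_g
  idx <- 1L + (u > cum1) + (u > cum2) + (u > cum3)
  c(BASE_A, BASE_C, BASE_G, BASE_T)[idx]
}

place_genes <- function(spec) {
  len <- spec$length
  if (spec$gene_density == 0) {
    return(empty_gene_table())
  }
  b1 <- round(spec$shift * len)
  b2 <- round(((spec$shift + spec$div) %% 1) * len)
  breaks <- sort(unique(c(b1, b2)))
  breaks <- breaks[breaks > 0 & breaks < len]
  margin <- 30L
  mean_glen <- 900
  mean_gap <- mean_glen * (1 - spec$gene_density) / spec$gene_density
  starts <- integer(0); ends <- integer(0); strands <- integer(0)
  pos <- 0L
  repeat {
    gap <- max(6L, round(stats::rexp(1, 1 / max(mean_gap, 1))))
    glen <- 3L * sample(150:450, 1L)
    s <- pos + gap
    e <- s + glen
    crossing <- breaks[breaks > s - margin & breaks < e + margin]
    if (length(crossing) > 0L) {
      pos <- crossing[1] + margin
      next
    }
    if (e > len - margin) break
    frac <- ((s / len) - spec$shift) %% 1
    leading_sense <- if (frac < spec$div) 1L else -1L
    strand <- if (stats::runif(1) < spec$leading_strand_gene_fraction) {
      leading_sense
    } else {
      -leading_sense
    }
    starts <- c(starts, s); ends <- c(ends, e); strands <- c(strands, strand)
    pos <- e
  }
  if (length(starts) == 0L) {
    return(empty_gene_table())
  }
  name <- sprintf("gene%04d", seq_along(starts))
  # call the gene closest to the planted origin breakpoint "dnaA"
  circ_dist <- pmin(abs(starts - b1), len - abs(starts - b1))
  name[which.min(circ_dist)] <- "dnaA"
  data.frame(seq_id = NA_character_, start = starts, end = ends,
             strand = strands, feature_type = "CDS", name = name,
             stringsAsFactors = FALSE)
}

# stamp start (ATG) and stop (TAA) codons onto the reference strand;
# returns the stamped positions
stamp_codons <- function(codes, genes) {
  atg <- utf8ToInt("ATG"); taa <- utf8ToInt("TAA")
  cat_rc <- utf8ToInt("CAT"); tta_rc <- utf8ToInt("TTA")
  stamped <- integer(0)
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]; e <- genes$end[i]
    if (genes$strand[i] > 0L) {
      codes[(s + 1L):(s + 3L)] <- atg
      codes[(e - 2L):e] <- taa
    } else {
      codes[(e - 2L):e] <- cat_rc       # revcomp(ATG)
      codes[(s + 1L):(s + 3L)] <- tta_rc # revcomp(TAA)
    }
    stamped <- c(stamped, (s + 1L):(s + 3L), (e - 2L):e)
  }
  list(codes = codes, stamped = stamped)
}

# re-draw gene-body G/C identities so the sense strand carries G with
# probability codon_g_fraction (plants gene-driven, Firmicute-style skew)
apply_codon_bias <- function(codes, genes, cgf, stochastic, protected) {
  prot <- logical(length(codes))
  prot[protected] <- TRUE
  for (i in seq_len(nrow(genes))) {
    idx <- (genes$start[i] + 1L):genes$end[i]
    idx <- idx[!prot[idx] & (codes[idx] == BASE_G | codes[idx] == BASE_C)]
    if (length(idx) == 0L) next
    sense_g <- if (stochastic) {
      stats::runif(length(idx)) < cgf
    } else {
      diff(c(0, floor(cumsum(rep(cgf, length(idx))) + 1e-9))) >= 1L
    }
    ref_g <- if (genes$strand[i] > 0L) sense_g else !sense_g
    codes[idx] <- ifelse(ref_g, BASE_G, BASE_C)
  }
  codes
}

# flip eligible positions so per-arc (G-C, T-A) totals match `target`;
# moves combine A<->G and T<->G exchanges, which span all four directions
repair_arc <- function(codes, arc_idx, eligible, d_gc, d_ta) {
  take <- function(base, n) {
    cand <- arc_idx[eligible[arc_idx] & codes[arc_idx] == base]
    if (length(cand) == 0L || n <= 0L) return(integer(0))
    cand[unique(round(seq(1, length(cand), length.out = min(n, length(cand)))))]
  }
  u <- (d_gc + d_ta) %/% 2L        # (+1,+1) moves: A->G (or G->A if negative)
  v <- d_gc - u                    # (+1,-1) moves: T->G (or G->T if negative)
  if (u > 0L) {
    idx <- take(BASE_A, u); codes[idx] <- BASE_G
  } else if (u < 0L) {
    idx <- take(BASE_G, -u); codes[idx] <- BASE_A
  }
  if (v > 0L) {
    idx <- take(BASE_T, v); codes[idx] <- BASE_G
  } else if (v < 0L) {
    idx <- take(BASE_G, -v); codes[idx] <- BASE_T
  }
  codes
}

#' Generate a synthetic genome with planted replichore structure
#'
#' Emits a chromosome whose per-arc base composition realizes the planted
#' leading/lagging G and T excess rates, together with non-overlapping CDS
#' annotations at the requested density and strand preference (lengths are
#' multiples of 3, first codon ATG, last codon TAA; the gene nearest the
#' planted origin is named `dnaA`). See the module comments for the two
#' emission modes. The returned ground truth records the spec together with
#' realized per-arc base counts and gene strand counts.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with elements `record` (a `sequence_record`), `genes` (gene
#'   table as from [read_gff3()]) and `truth` (ground-truth list).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  len <- spec$length
  rates <- arc_rates(spec)
  p_g <- 0.25 + rates$gc / 2
  p_c <- 0.25 - rates$gc / 2
  p_t <- 0.25 + rates$ta / 2
  p_a <- 0.25 - rates$ta / 2

  withr::with_seed(spec$seed, {
    codes <- if (spec$noise == "none") {
      emit_deterministic(p_a, p_c, p_g, p_t, len)
    } else {
      emit_stochastic(p_a, p_c, p_g, p_t, len)
    }
    genes <- place_genes(spec)
    accession <- sprintf("SYN%06d", spec$seed %% 1000000L)
    if (nrow(genes) > 0L) {
      genes$seq_id <- accession
      pre_gc <- c(sum((codes == BASE_G)[rates$leading]) -
                    sum((codes == BASE_C)[rates$leading]),
                  sum((codes == BASE_G)[!rates$leading]) -
                    sum((codes == BASE_C)[!rates$leading]))
      pre_ta <- c(sum((codes == BASE_T)[rates$leading]) -
                    sum((codes == BASE_A)[rates$leading]),
                  sum((codes == BASE_T)[!rates$leading]) -
                    sum((codes == BASE_A)[!rates$leading]))
      st <- stamp_codons(codes, genes)
      codes <- st$codes
      if (spec$codon_g_fraction != 0.5) {
        codes <- apply_codon_bias(codes, genes, spec$codon_g_fraction,
                                  stochastic = spec$noise != "none",
                                  protected = st$stamped)
      } else if (spec$noise == "none") {
        # repair codon-stamping damage so planted per-arc totals stay exact
        eligible <- rep(TRUE, len)
        eligible[st$stamped] <- FALSE
        arcs <- list(which(rates$leading), which(!rates$leading))
        for (k in 1:2) {
          arc <- arcs[[k]]
          d_gc <- pre_gc[k] - (sum(codes[arc] == BASE_G) -
                                 sum(codes[arc] == BASE_C))
          d_ta <- pre_ta[k] - (sum(codes[arc] == BASE_T) -
                                 sum(codes[arc] == BASE_A))
          codes <- repair_arc(codes, arc, eligible, d_gc, d_ta)
        }
      }
    }
  })

  record <- sequence_record(
    accession = accession,
    description = sprintf(
      "synthetic chromosome L=%d div=%.3f shift=%.3f seed=%d",
      len, spec$div, spec$shift, spec$seed),
    residues = intToUtf8(codes)
  )
  leading <- rates$leading
  truth <- list(
    spec = spec,
    arc_counts = list(
      leading = c(A = sum(codes[leading] == BASE_A),
                  C = sum(codes[leading] == BASE_C),
                  G = sum(codes[leading] == BASE_G),
                  T = sum(codes[leading] == BASE_T)),
      lagging = c(A = sum(codes[!leading] == BASE_A),
                  C = sum(codes[!leading] == BASE_C),
                  G = sum(codes[!leading] == BASE_G),
                  T = sum(codes[!leading] == BASE_T))
    ),
    gene_count = nrow(genes),
    coding_nt = if (nrow(genes) > 0L) sum(genes$end - genes$start) else 0L,
    plus_strand_genes = if (nrow(genes) > 0L) sum(genes$strand > 0L) else 0L
  )
  list(record = record, genes = genes, truth = truth)
}

#' Write a simulated genome to FASTA + GFF3 + ground-truth CSV
#'
#' @param spec A `synthetic_spec`.
#' @param out_dir Output directory (created if needed).
#' @param basename File stem for the three outputs.
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(spec, out_dir, basename = "synthetic") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(spec)
  fa <- file.path(out_dir, paste0(basename, ".fasta"))
  gff <- file.path(out_dir, paste0(basename, ".gff3"))
  truth <- file.path(out_dir, paste0(basename, "_truth.csv"))
  write_fasta(list(sim$record), fa)
  write_gff3(sim$genes, gff)
  td <- data.frame(
    accession = sim$record$accession,
    length = spec$length,
    gc_alpha1 = spec$gc_alpha1, gc_alpha2 = spec$gc_alpha2,
    ta_alpha1 = spec$ta_alpha1, ta_alpha2 = spec$ta_alpha2,
    div = spec$div, shift = spec$shift,
    gene_density = spec$gene_density,
    leading_strand_gene_fraction = spec$leading_strand_gene_fraction,
    codon_g_fraction = spec$codon_g_fraction,
    noise = spec$noise, seed = spec$seed,
    gene_count = sim$truth$gene_count,
    coding_nt = sim$truth$coding_nt,
    plus_strand_genes = sim$truth$plus_strand_genes
  )
  utils::write.csv(td, truth, row.names = FALSE, quote = FALSE)
  invisible(c(fasta = fa, gff3 = gff, truth = truth))
}
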