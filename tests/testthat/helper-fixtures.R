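# Shared fixtures and independent oracles. Everything here is deliberately
# naive (per-position loops, lm-based slopes) so it cannot share bugs with
# the vectorized implementation under test.

make_record <- function(residues, accession = "X", description = "") {
  sequence_record(accession = accession, description = description,
                  residues = residues)
}

gene_row <- function(seq_id, start, end, strand, name = "") {
  data.frame(seq_id = seq_id, start = as.integer(start), end = as.integer(end),
             strand = as.integer(strand), feature_type = "CDS", name = name,
             stringsAsFactors = FALSE)
}

write_tmp_fasta <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

write_tmp_gff <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".gff3.gz" else ".gff3")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(c("##gff-version 3", lines), con)
  close(con)
  path
}

# a small random genome with non-overlapping genes, for oracle comparisons
random_toy_genome <- function(len = 6000L, n_genes = 4L, seed = 1L) {
  withr::with_seed(seed, {
    residues <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
    bounds <- sort(sample(seq(10L, len - 10L, by = 3L), 2L * n_genes))
    genes <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      s <- bounds[2L * i - 1L]
      e <- bounds[2L * i]
      e <- s + max(3L, ((e - s) %/% 3L) * 3L)
      gene_row("X", s, min(e, len), sample(c(1L, -1L), 1L))
    }))
    list(record = make_record(residues), genes = genes)
  })
}

# per-position re-count oracle for scan_chromosome: walks the sequence one
# nucleotide at a time, classifying each position independently
brute_scan <- function(record, genes, interval = 4096L) {
  chars <- strsplit(record$residues, NULL)[[1]]
  len <- length(chars)
  cls <- rep(3L, len)
  strand_sum <- integer(len)
  genic <- logical(len)
  if (nrow(genes) > 0L) {
    genes <- genes[order(genes$start), , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      for (p in (genes$start[i] + 1L):genes$end[i]) {
        strand_sum[p] <- strand_sum[p] + genes$strand[i]
        genic[p] <- TRUE
      }
    }
    assigned <- logical(len)
    for (i in seq_len(nrow(genes))) {
      glen <- genes$end[i] - genes$start[i]
      if (glen %% 3L != 0L) next
      for (off in 0:(glen - 1L)) {
        p <- genes$start[i] + off + 1L
        if (assigned[p]) next
        cls[p] <- if (genes$strand[i] > 0L) off %% 3L else (glen - 1L - off) %% 3L
        assigned[p] <- TRUE
      }
    }
  }
  cp <- if (len < interval) integer(0) else seq.int(interval, len, by = interval)
  if (length(cp) == 0L || cp[length(cp)] != len) cp <- c(cp, len)
  d_gc <- (chars == "G") - (chars == "C")
  d_ta <- (chars == "T") - (chars == "A")
  snap <- function(x) cumsum(x)[cp]
  data.frame(
    abspos = cp,
    gcskew = snap(d_gc), taskew = snap(d_ta),
    gcskew0 = snap(d_gc * (cls == 0L)), gcskew1 = snap(d_gc * (cls == 1L)),
    gcskew2 = snap(d_gc * (cls == 2L)), gcskewNG = snap(d_gc * (cls == 3L)),
    taskew0 = snap(d_ta * (cls == 0L)), taskew1 = snap(d_ta * (cls == 1L)),
    taskew2 = snap(d_ta * (cls == 2L)), taskewNG = snap(d_ta * (cls == 3L)),
    pospos = snap(strand_sum), ngcount = snap(!genic),
    acount = snap(chars == "A"), ccount = snap(chars == "C"),
    gcount = snap(chars == "G"), tcount = snap(chars == "T")
  )
}

# independent model evaluation: per-position slope accumulation
brute_model_eval <- function(alpha1, alpha2, div, shift, len, positions) {
  slopes <- numeric(len)
  for (p in 0:(len - 1L)) {
    frac <- ((p / len) - shift) %% 1
    slopes[p + 1L] <- if (frac < div) alpha1 else -alpha2
  }
  vapply(positions, function(p) if (p == 0) 0 else sum(slopes[seq_len(p)]), 0)
}

# exhaustive (div, shift) grid with lm-based slopes: the fit-optimality oracle
grid_fit_rmse <- function(track, len, resolution = 64L) {
  pos <- track$positions
  obs <- track$values
  best <- Inf
  for (di in seq_len(resolution - 1L)) {
    for (si in 0:(resolution - 1L)) {
      div <- di / resolution
      shift <- si / resolution
      lead <- vapply(pos, function(p) {
        # leading-arc overlap by brute interval arithmetic on unit circle
        lo <- shift; hi <- shift + div
        pf <- p / len
        ov <- max(0, min(pf, min(hi, 1)) - lo)
        if (hi > 1) ov <- ov + min(pf, hi - 1)
        ov * len
      }, 0)
      lag <- pos - lead
      fit <- stats::lm.fit(cbind(lead, -lag), obs)
      rmse <- sqrt(mean(fit$residuals^2))
      if (rmse < best) best <- rmse
    }
  }
  best
}
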