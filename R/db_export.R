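# CSV serialisation of scan profiles and fits.
#
# Five products, mirroring the published database layout:
#   skplot.csv   - all checkpoint counters for all chromosomes
#   results.csv  - one row of fitted parameters per chromosome
#   genomes.csv  - per-chromosome summary (counts, codons, taxonomy, dnaA)
#   codongc.csv  - coding-nucleotide composition, overall and per strand
#   <acc>_fit.csv - observed vs predicted skews at checkpoint resolution
# The published field list names four codon-position skew columns
# (`gcskew0-3`) while three codon positions plus a non-coding bucket are
# described; we emit `gcskew0..2` plus `gcskewNG` (and likewise for TA),
# i.e. slot 3 is the non-coding bucket. Floats are written with 6 significant
# digits, integers unpadded, so every writer round-trips value-identically.

SKEW_KEYS <- c("ta", "gc0", "gc1", "gc2", "ta0", "ta1", "ta2",
               "gcng", "tang", "sb")

SKPLOT_COLUMNS <- c(
  "name", "abspos", "relpos", "gcskew", "taskew",
  "gcskew0", "gcskew1", "gcskew2", "taskew0", "taskew1", "taskew2",
  "gcskewNG", "taskewNG", "pospos", "ngcount",
  "acount", "ccount", "gcount", "tcount"
)

RESULTS_COLUMNS <- c(
  "name", "div", "shift",
  "alpha1gc", "alpha2gc", "gcRMS",
  as.vector(t(outer(SKEW_KEYS, c("alpha1%s", "alpha2%s", "%sRMS"),
                    function(k, f) sprintf(f, k))))
)

GENOMES_COLUMNS <- c(
  "name", "fullname", "acount", "ccount", "gcount", "tcount", "plasmid",
  "realm1", "realm2", "realm3", "realm4", "realm5",
  "protgenecount", "stopTAG", "stopTAA", "stopTGA", "stopXXX",
  "startATG", "startGTG", "startTTG", "startXXX", "dnaApos"
)

CODONGC_COLUMNS <- c(
  "name", "afrac", "cfrac", "gfrac", "tfrac",
  "leadafrac", "leadcfrac", "leadgfrac", "leadtfrac",
  "lagafrac", "lagcfrac", "laggfrac", "lagtfrac",
  "ggcfrac", "cgcfrac", "atafrac", "ttafrac"
)

#' Column schemas of the CSV products
#'
#' @param name One of `"skplot"`, `"results"`, `"genomes"`, `"codongc"`,
#'   `"fit"`.
#' @return Ordered character vector of column names.
#' @export
csv_schema <- function(name = c("skplot", "results", "genomes", "codongc",
                                "fit")) {
  name <- match.arg(name)
  switch(name,
    skplot = SKPLOT_COLUMNS,
    results = RESULTS_COLUMNS,
    genomes = GENOMES_COLUMNS,
    codongc = CODONGC_COLUMNS,
    fit = c("abspos", "relpos",
            as.vector(t(outer(c("gc", SKEW_KEYS), c("%sskew", "pred%sskew"),
                              function(k, f) sprintf(f, k)))))
  )
}

# 6 significant digits for doubles, unpadded integers
fmt_cell <- function(x) {
  if (is.double(x)) {
    out <- formatC(signif(x, 6), format = "g", digits = 6)
    out[!is.finite(x)] <- as.character(x[!is.finite(x)])
    trimws(out)
  } else {
    as.character(x)
  }
}

write_schema_csv <- function(df, columns, path) {
  stopifnot(identical(names(df), columns))
  qcols <- which(vapply(df, is.character, TRUE))
  out <- df
  for (j in seq_along(out)) out[[j]] <- fmt_cell(out[[j]])
  utils::write.csv(out, path, row.names = FALSE,
                   quote = if (length(qcols)) qcols else FALSE)
  invisible(path)
}

#' Write the per-checkpoint counters of one or more chromosomes
#'
#' @param profiles List of `scan_profile` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_skplot <- function(profiles, path) {
  if (inherits(profiles, "scan_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0L)
  rows <- lapply(profiles, function(p) {
    cbind(data.frame(name = p$accession), p$checkpoints)
  })
  df <- do.call(rbind, rows)[, SKPLOT_COLUMNS]
  write_schema_csv(df, SKPLOT_COLUMNS, path)
}

result_row <- function(res) {
  stopifnot(inherits(res, "chromosome_result"))
  row <- list(name = res$accession, div = res$div, shift = res$shift,
              alpha1gc = res$gc$alpha1, alpha2gc = res$gc$alpha2,
              gcRMS = res$gc$rms)
  for (k in SKEW_KEYS) {
    f <- res$constrained[[k]]
    if (is.null(f)) {
      warning("missing constrained fit '", k, "' for ", res$accession)
      f <- list(alpha1 = NA_real_, alpha2 = NA_real_, rms = NA_real_)
    }
    row[[sprintf("alpha1%s", k)]] <- f$alpha1
    row[[sprintf("alpha2%s", k)]] <- f$alpha2
    row[[sprintf("%sRMS", k)]] <- f$rms
  }
  as.data.frame(row)
}

#' Write the fitted-parameter table
#'
#' One row per chromosome; `div` and `shift` appear once (they come from the
#' GC fit and constrain all other skews).
#'
#' @param results List of `chromosome_result` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "chromosome_result")) results <- list(results)
  stopifnot(length(results) > 0L)
  df <- do.call(rbind, lapply(results, result_row))[, RESULTS_COLUMNS]
  write_schema_csv(df, RESULTS_COLUMNS, path)
}

#' Write the per-chromosome summary table
#'
#' @param records List of `sequence_record` objects.
#' @param tallies List of codon tallies (from [tally_codons()]), aligned with
#'   `records`.
#' @param dnaA Integer vector of DnaA positions (from [find_dnaA()]), aligned
#'   with `records`.
#' @param taxonomy Optional `taxonomy_map` (placeholders used when `NULL`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(records, tallies, dnaA, taxonomy = NULL, path) {
  stopifnot(length(records) == length(tallies),
            length(records) == length(dnaA))
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    ints <- utf8ToInt(r$residues)
    realms <- taxonomy_lookup(taxonomy, r$accession)
    t <- tallies[[i]]
    data.frame(
      name = r$accession, fullname = trimws(paste(r$accession, r$description)),
      acount = sum(ints == BASE_A), ccount = sum(ints == BASE_C),
      gcount = sum(ints == BASE_G), tcount = sum(ints == BASE_T),
      plasmid = as.integer(r$is_plasmid),
      realm1 = realms[1], realm2 = realms[2], realm3 = realms[3],
      realm4 = realms[4], realm5 = realms[5],
      protgenecount = t$protgenecount,
      stopTAG = t$stopTAG, stopTAA = t$stopTAA, stopTGA = t$stopTGA,
      stopXXX = t$stopXXX,
      startATG = t$startATG, startGTG = t$startGTG, startTTG = t$startTTG,
      startXXX = t$startXXX,
      dnaApos = dnaA[i]
    )
  })
  df <- do.call(rbind, rows)[, GENOMES_COLUMNS]
  write_schema_csv(df, GENOMES_COLUMNS, path)
}

#' Write the coding-composition table
#'
#' @param compositions Named list: accession -> composition list from
#'   [coding_composition()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codongc <- function(compositions, path) {
  stopifnot(length(compositions) > 0L, !is.null(names(compositions)))
  rows <- lapply(names(compositions), function(acc) {
    as.data.frame(c(list(name = acc), compositions[[acc]]))
  })
  df <- do.call(rbind, rows)[, CODONGC_COLUMNS]
  write_schema_csv(df, CODONGC_COLUMNS, path)
}

#' Write one chromosome's observed-vs-predicted fit table
#'
#' Pairs every observed skew column with its model prediction (`gcskew` /
#' `predgcskew`, etc.) at checkpoint resolution. Predictions use the GC fit's
#' four parameters for `gc` and the shared `div`/`shift` with each skew's own
#' slopes for the rest.
#'
#' @param profile A `scan_profile`.
#' @param result The matching `chromosome_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(profile, result, path) {
  stopifnot(inherits(profile, "scan_profile"),
            inherits(result, "chromosome_result"),
            profile$accession == result$accession)
  cp <- profile$checkpoints
  pos <- cp$abspos
  cols <- list(abspos = pos, relpos = cp$relpos)
  track_col <- c(gc = "gcskew", ta = "taskew", gc0 = "gcskew0",
                 gc1 = "gcskew1", gc2 = "gcskew2", ta0 = "taskew0",
                 ta1 = "taskew1", ta2 = "taskew2", gcng = "gcskewNG",
                 tang = "taskewNG", sb = "pospos")
  for (k in names(track_col)) {
    obs <- as.numeric(cp[[track_col[[k]]]])
    params <- if (k == "gc") {
      result$gc
    } else {
      f <- result$constrained[[k]]
      fit_params(f$alpha1, f$alpha2, div = result$div, shift = result$shift)
    }
    pred <- model_eval(params, profile$length, pos)
    cols[[sprintf("%sskew", k)]] <- obs
    cols[[sprintf("pred%sskew", k)]] <- pred
  }
  df <- as.data.frame(cols)
  write_schema_csv(df, csv_schema("fit"), path)
}
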