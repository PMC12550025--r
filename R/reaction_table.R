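#' Read a tabular reaction file into reaction records
#'
#' Parses a SURF-like delimited table (columns `reactant_1..n`, `product`,
#' `catalyst`, `reagent_1..n`, `time_h`, `yield` by default) into a
#' reaction-record data frame. All SMILES are canonicalized; rows missing a
#' mandatory role, with non-positive reaction time, an unparseable SMILES,
#' or a missing target are dropped, and every drop is logged with a reason
#' in the `drop_log` attribute.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param dialect named list mapping logical fields to columns:
#'   `reactant_prefix`, `product`, `catalyst`, `reagent_prefix`, `time`,
#'   `target`, `target_kind` (a fixed tag for all rows).
#' @return a `data.frame` of records with columns `reactants` (list),
#'   `product`, `catalyst`, `reagents` (list), `time_h`, `target`,
#'   `target_kind`, `catalyst_mw`, `catalyst_atom_count`, plus a
#'   `drop_log` attribute (`data.frame` with `row`, `reason`).
#' @export
parse_reaction_table <- function(path, dialect = surf_dialect()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  rcols <- grep(paste0("^", dialect$reactant_prefix), names(tab), value = TRUE)
  gcols <- grep(paste0("^", dialect$reagent_prefix), names(tab), value = TRUE)
  need <- c(dialect$product, dialect$catalyst, dialect$time, dialect$target)
  if (!length(rcols) || !all(need %in% names(tab))) {
    stop("missing mandatory column(s): ",
         paste(setdiff(c(need, paste0(dialect$reactant_prefix, "1")),
                       names(tab)), collapse = ", "))
  }
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  drops <- list()
  note <- function(row, why) drops[[length(drops) + 1L]] <<- data.frame(row = row, reason = why)

  records <- reaction_records()
  for (r in seq_len(nrow(tab))) {
    reac <- as.character(unlist(tab[r, rcols])); reac <- reac[!blank(reac)]
    regs <- if (length(gcols)) as.character(unlist(tab[r, gcols])) else character()
    regs <- regs[!blank(regs)]
    prod <- as.character(tab[r, dialect$product])
    cata <- as.character(tab[r, dialect$catalyst])
    tm <- suppressWarnings(as.numeric(tab[r, dialect$time]))
    tgt <- suppressWarnings(as.numeric(tab[r, dialect$target]))
    if (!length(reac)) { note(r, "missing_reactant"); next }
    if (blank(prod)) { note(r, "missing_product"); next }
    if (blank(cata)) { note(r, "missing_catalyst"); next }
    if (is.na(tm) || tm <= 0) { note(r, "nonpositive_time"); next }
    if (is.na(tgt)) { note(r, "missing_target"); next }
    smis <- c(reac, regs, prod, cata)
    can <- canonical_smiles(smis)
    if (anyNA(can)) { note(r, "unparseable_smiles"); next }
    nr <- length(reac); ng <- length(regs)
    cat_can <- can[nr + ng + 2L]
    cmol <- parse_smiles(cat_can)[[1]]
    if (is.null(cmol)) { note(r, "unparseable_smiles"); next }
    records <- rbind(records, new_reaction_record(
      reactants = can[seq_len(nr)],
      product = can[nr + ng + 1L],
      catalyst = cat_can,
      reagents = if (ng) can[nr + seq_len(ng)] else character(),
      time_h = tm, target = tgt, target_kind = dialect$target_kind,
      catalyst_mw = mol_mw(cmol), catalyst_atom_count = mol_natoms(cmol)))
  }
  attr(records, "drop_log") <- if (length(drops)) do.call(rbind, drops)
                               else data.frame(row = integer(), reason = character())
  records
}

#' Default SURF-like column mapping
#' @return a named list usable as the `dialect` of [parse_reaction_table()].
#' @export
surf_dialect <- function() {
  list(reactant_prefix = "reactant_", product = "product",
       catalyst = "catalyst", reagent_prefix = "reagent_",
       time = "time_h", target = "yield", target_kind = "yield")
}

# Empty record frame with the canonical column layout.
reaction_records <- function() {
  data.frame(reactants = I(list()), product = character(),
             catalyst = character(), reagents = I(list()),
             time_h = numeric(), target = numeric(),
             target_kind = character(), catalyst_mw = numeric(),
             catalyst_atom_count = integer())
}

new_reaction_record <- function(reactants, product, catalyst, reagents,
                                time_h, target, target_kind,
                                catalyst_mw, catalyst_atom_count) {
  data.frame(reactants = I(list(reactants)), product = product,
             catalyst = catalyst, reagents = I(list(reagents)),
             time_h = time_h, target = target, target_kind = target_kind,
             catalyst_mw = catalyst_mw,
             catalyst_atom_count = as.integer(catalyst_atom_count))
}

# Order-insensitive duplicate key over roles and time.
.record_keys <- function(records) {
  vapply(seq_len(nrow(records)), function(r) {
    paste(paste(sort(records$reactants[[r]]), collapse = "."),
          records$product[r], records$catalyst[r],
          paste(sort(records$reagents[[r]]), collapse = "."),
          format(records$time_h[r], digits = 12), sep = "|")
  }, character(1))
}

#' Average duplicate reaction records
#'
#' Records sharing the same reactant multiset, product, catalyst, reagent
#' multiset, and reaction time collapse to a single record whose target is
#' the arithmetic mean of the group.
#'
#' @param records a reaction-record data frame.
#' @return deduplicated records (first occurrence order preserved).
#' @export
deduplicate_average <- function(records) {
  if (!nrow(records)) return(records)
  keys <- .record_keys(records)
  first <- !duplicated(keys)
  means <- tapply(records$target, keys, mean)
  out <- records[first, , drop = FALSE]
  out$target <- as.numeric(means[keys[first]])
  rownames(out) <- NULL
  .log_drops(out, records, "duplicate_averaged")
}

#' Interquartile-range outlier filter
#'
#' A record survives when, for every selected field, its value lies inside
#' `[Q1 - k*IQR, Q3 + k*IQR]` with quartiles computed over the input by
#' linear interpolation (quantile type 7).
#'
#' @param records a reaction-record data frame.
#' @param fields subset of `catalyst_mw`, `catalyst_atom_count`, `target`.
#' @param k whisker multiplier (default 1.5).
#' @return filtered records.
#' @export
iqr_filter <- function(records,
                       fields = c("catalyst_mw", "catalyst_atom_count", "target"),
                       k = 1.5) {
  stopifnot(k > 0, all(fields %in% names(records)))
  if (nrow(records) < 4L) {
    warning("fewer than 4 records: IQR filter skipped")
    return(records)
  }
  keep <- rep(TRUE, nrow(records))
  for (f in fields) {
    x <- records[[f]]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    keep <- keep & x >= q[1] - k * iqr & x <= q[2] + k * iqr
  }
  .log_drops(records[keep, , drop = FALSE], records, "iqr_outlier")
}

#' Clip yield targets to a range
#'
#' Yield-kind targets are clipped to `[low, high]` (defaults 0 and 100);
#' non-yield targets pass through untouched.
#'
#' @param records a reaction-record data frame.
#' @param low,high clipping bounds.
#' @return records with clipped targets.
#' @export
clip_target <- function(records, low = 0, high = 100) {
  y <- records$target_kind == "yield"
  records$target[y] <- pmin(pmax(records$target[y], low), high)
  records
}

#' Downsample overrepresented catalysts
#'
#' Keeps at most `max_per_catalyst` records per canonical catalyst, chosen
#' uniformly at random under `seed`. The default cap is 1 percent of the
#' input (at least 1), so no single catalyst dominates the curated set.
#'
#' @param records a reaction-record data frame.
#' @param max_per_catalyst cap per catalyst (default `ceiling(n / 100)`).
#' @param seed integer seed.
#' @return downsampled records (input order preserved).
#' @export
downsample_overrepresented <- function(records, max_per_catalyst = NULL,
                                       seed = 1L) {
  if (!nrow(records)) return(records)
  if (is.null(max_per_catalyst)) {
    max_per_catalyst <- max(1L, ceiling(nrow(records) / 100))
  }
  stopifnot(max_per_catalyst >= 1L)
  rng <- .seeded_rng(seed)
  keep <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), records$catalyst)) {
    if (length(idx) <= max_per_catalyst) keep[idx] <- TRUE
    else keep[idx[rng$sample(length(idx), max_per_catalyst)]] <- TRUE
  }
  .log_drops(records[keep, , drop = FALSE], records, "downsampled")
}

#' Split records into train/validation/test sets
#'
#' Random, seed-reproducible, exhaustive and disjoint partition with sizes
#' within rounding of the requested percentages (default 90:5:5).
#'
#' @param records a reaction-record data frame.
#' @param ratios three percentages summing to 100.
#' @param seed integer seed.
#' @return an object of class `dataset_split`: list with `train`,
#'   `validation`, `test`, `ratios`, `seed`.
#' @export
split_dataset <- function(records, ratios = c(90, 5, 5), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 100) > 1e-9) {
    stop("ratios must be three percentages summing to 100")
  }
  n <- nrow(records)
  rng <- .seeded_rng(seed)
  perm <- if (n) rng$sample(n) else integer()
  cuts <- round(cumsum(ratios) / 100 * n)
  sizes <- diff(c(0L, cuts))
  idx <- split(perm, rep(1:3, times = sizes))
  pick <- function(k) {
    out <- records[sort(idx[[as.character(k)]] %||% integer()), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(list(train = pick(1), validation = pick(2), test = pick(3),
                 ratios = ratios, seed = seed),
            class = "dataset_split")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split %s: %d/%d/%d records (seed %d)>\n",
              paste(x$ratios, collapse = ":"), nrow(x$train),
              nrow(x$validation), nrow(x$test), x$seed))
  invisible(x)
}

#' Full curation pipeline
#'
#' Runs deduplication, IQR outlier removal, yield clipping and catalyst
#' downsampling in the canonical order, accumulating a drop log.
#'
#' @param records parsed reaction records.
#' @param iqr_k IQR whisker multiplier.
#' @param max_per_catalyst downsampling cap (`NULL` = 1 percent rule).
#' @param seed seed for downsampling.
#' @return curated records with a `drop_log` attribute.
#' @export
curate_reactions <- function(records, iqr_k = 1.5, max_per_catalyst = NULL,
                             seed = 1L) {
  out <- deduplicate_average(records)
  out <- iqr_filter(out, k = iqr_k)
  out <- clip_target(out)
  downsample_overrepresented(out, max_per_catalyst, seed)
}

# Append dropped-row reasons to the drop_log attribute carried on records.
.log_drops <- function(kept, input, reason) {
  log <- attr(input, "drop_log") %||%
    data.frame(row = integer(), reason = character())
  n_drop <- nrow(input) - nrow(kept)
  if (n_drop > 0) {
    log <- rbind(log, data.frame(row = rep(NA_integer_, n_drop),
                                 reason = rep(reason, n_drop)))
  }
  rownames(kept) <- NULL
  attr(kept, "drop_log") <- log
  kept
}
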