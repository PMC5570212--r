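# Affinity-change dataset handling: reading/validation, reverse-mutation
# augmentation and leakage-safe cross-validation folds.
#
# Sign convention throughout: negative ddG = the mutation reduces binding
# affinity.

DATASET_COLUMNS <- c("structure_ref", "chain", "mutation", "na_type",
                     "ddg_exp")

#' Read an affinity-change dataset
#'
#' Reads a TSV with one single-point mutation per row. Mandatory columns:
#' `structure_ref`, `chain`, `mutation` (string form, e.g. `"R273C"`),
#' `na_type` (`RNA`/`ssDNA`/`dsDNA`), `ddg_exp` (kcal/mol, signed).
#' Optional: `ddg_stability`, `direction`, `partner_id`, `source`.
#' Differently named columns can be mapped via `col_map`. Rows whose
#' mutation string does not parse or whose ddG is missing are dropped with
#' a row-numbered message; a composition summary is attached as the
#' `"summary"` attribute and printed.
#'
#' @param path TSV file path.
#' @param col_map optional named character vector mapping file column
#'   names to schema names, e.g. `c(PDB = "structure_ref")`.
#' @return data frame of validated records (class `na_dataset`), columns
#'   as above plus `direction` (default `"forward"`) and `partner_id`.
#' @export
read_dataset <- function(path, col_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- names(tab) %in% names(col_map)
    names(tab)[hit] <- col_map[names(tab)[hit]]
  }
  missing_cols <- setdiff(DATASET_COLUMNS, names(tab))
  if (length(missing_cols) > 0)
    stopf("dataset is missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))

  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({
      mutation_spec(tab$mutation[i], tab$chain[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      message(sprintf("read_dataset: row %d rejected: bad mutation string '%s'",
                      i, tab$mutation[i]))
      keep[i] <- FALSE
    } else if (is.na(suppressWarnings(as.numeric(tab$ddg_exp[i])))) {
      message(sprintf("read_dataset: row %d rejected: missing/non-numeric ddg_exp", i))
      keep[i] <- FALSE
    } else if (!tab$na_type[i] %in% c("RNA", "ssDNA", "dsDNA")) {
      message(sprintf("read_dataset: row %d rejected: unknown na_type '%s'",
                      i, tab$na_type[i]))
      keep[i] <- FALSE
    }
  }
  rec <- tab[keep, , drop = FALSE]
  rec$ddg_exp <- as.numeric(rec$ddg_exp)
  if (is.null(rec$direction)) rec$direction <- "forward"
  if (is.null(rec$partner_id)) rec$partner_id <- seq_len(nrow(rec))
  if (is.null(rec$source)) rec$source <- "train"
  rownames(rec) <- NULL

  smry <- dataset_summary(rec)
  message(paste(utils::capture.output(print(smry)), collapse = "\n"))
  attr(rec, "summary") <- smry
  class(rec) <- c("na_dataset", "data.frame")
  rec
}

#' Composition summary of a dataset
#'
#' @param rec records data frame.
#' @return list: `n`, `n_structures`, `n_reducing` (ddG < 0),
#'   `n_increasing`, `per_type` (records and structures per na_type).
#' @export
dataset_summary <- function(rec) {
  per_type <- lapply(split(rec, rec$na_type), function(s)
    c(n = nrow(s), n_structures = length(unique(s$structure_ref))))
  out <- list(n = nrow(rec),
              n_structures = length(unique(rec$structure_ref)),
              n_reducing = sum(rec$ddg_exp < 0),
              n_increasing = sum(rec$ddg_exp > 0),
              per_type = per_type)
  class(out) <- "na_dataset_summary"
  out
}

#' @export
print.na_dataset_summary <- function(x, ...) {
  cat(sprintf("dataset: %d mutations across %d structures (%d reducing, %d increasing affinity)\n",
              x$n, x$n_structures, x$n_reducing, x$n_increasing))
  for (t in names(x$per_type))
    cat(sprintf("  %-6s %3d mutations / %d structures\n", t,
                x$per_type[[t]]["n"], x$per_type[[t]]["n_structures"]))
  invisible(x)
}

#' Write a dataset table
#'
#' @param rec records data frame.
#' @param path output TSV.
#' @export
write_dataset <- function(rec, path) {
  utils::write.table(as.data.frame(rec), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reverse-mutation augmentation
#'
#' Binding free energy is a state function, so the ddG of the reverse
#' mutation (mutant to wild type) is the negation of the forward ddG.
#' Each forward record gains a reverse partner with wild-type and mutant
#' letters swapped, ddG negated, `direction = "reverse"` and a shared
#' `partner_id`. When a modelled mutant structure is available (via
#' `mutant_structures`, named by the forward record's
#' `structure_ref:mutation`), the reverse record points at it and is
#' flagged `modeled = TRUE`; otherwise it keeps the wild-type structure
#' and the featurizer uses the change-vector route.
#'
#' @param rec forward records only (augmenting an already augmented set is
#'   an error).
#' @param mutant_structures optional named character vector of modelled
#'   mutant structure refs.
#' @return augmented records, forward rows first, then reverse rows.
#' @export
augment_reverse <- function(rec, mutant_structures = NULL) {
  if (!all(rec$direction == "forward"))
    stopf("augment_reverse expects forward records only (already augmented?)")
  if (anyDuplicated(rec$partner_id))
    stopf("duplicate partner_id in forward records")
  rev <- rec
  rev$mutation <- vapply(seq_len(nrow(rec)), function(i) {
    m <- mutation_spec(rec$mutation[i], rec$chain[i])
    paste0(m$mut, m$resno, m$insert, m$wt)
  }, character(1))
  rev$ddg_exp <- -rec$ddg_exp
  if (!is.null(rec$ddg_stability)) rev$ddg_stability <- -rec$ddg_stability
  rev$direction <- "reverse"
  rev$modeled <- FALSE
  if (!is.null(mutant_structures)) {
    key <- paste0(rec$structure_ref, ":", rec$mutation)
    hit <- key %in% names(mutant_structures)
    rev$structure_ref[hit] <- mutant_structures[key[hit]]
    rev$modeled[hit] <- TRUE
  }
  fwd <- rec
  fwd$modeled <- NA
  out <- rbind(as.data.frame(fwd), as.data.frame(rev))
  rownames(out) <- NULL
  class(out) <- c("na_dataset", "data.frame")
  out
}

#' Leakage-safe cross-validation folds
#'
#' Assigns forward/reverse pairs — never individual records — to `k`
#' folds by a seeded shuffle, so a mutation and its negated twin can never
#' end up on opposite sides of a train/test split. Pair counts per fold
#' differ by at most one. With `by_structure = TRUE` all mutations of one
#' complex are kept in one fold instead (structure-level leakage control);
#' fold sizes are then balanced greedily by record count.
#'
#' @param rec (augmented) records.
#' @param k number of folds.
#' @param seed integer seed; same seed, same assignment.
#' @param by_structure group by `structure_ref` instead of partner pairs.
#' @return integer vector of fold indices (0 to k-1), one per record.
#' @export
make_folds <- function(rec, k = 10, seed = 1, by_structure = FALSE) {
  group <- if (by_structure) rec$structure_ref else rec$partner_id
  ids <- unique(group)
  if (k > length(ids))
    stopf("k = %d exceeds the number of assignable groups (%d)", k, length(ids))
  if (by_structure) {
    # greedy balance by record count, deterministic given seed
    sizes <- table(group)[as.character(ids)]
    ord <- with_seed(seed, sample(seq_along(ids)))
    ids <- ids[ord][order(-sizes[ord])]
    load <- numeric(k)
    fold_of <- integer(length(ids)); names(fold_of) <- as.character(ids)
    for (id in as.character(ids)) {
      f <- which.min(load)
      fold_of[id] <- f - 1L
      load[f] <- load[f] + sizes[id]
    }
  } else {
    shuffled <- ids[with_seed(seed, sample(length(ids)))]
    fold_of <- (seq_along(shuffled) - 1L) %% k
    names(fold_of) <- as.character(shuffled)
  }
  unname(fold_of[as.character(group)])
}
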