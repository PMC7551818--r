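#' Condensed Fukui functions and dual descriptor
#'
#' Condenses the Fukui functions to atoms by finite differences of atomic
#' populations across the N-1, N and N+1 electron species. With partial
#' charges q (population p = -q, so only charge differences matter):
#'
#' * `f_plus_k  = q_neutral_k - q_anion_k`  (susceptibility to nucleophilic
#'   attack: where the added electron goes);
#' * `f_minus_k = q_cation_k - q_neutral_k` (susceptibility to electrophilic
#'   attack: where the removed electron came from);
#' * `f_zero_k  = (f_plus_k + f_minus_k) / 2` (radical attack);
#' * `dual_k    = f_plus_k - f_minus_k`.
#'
#' Sign convention: `dual > 0` marks sites favored for nucleophilic attack
#' (electron-accepting regions), `dual < 0` sites favored for electrophilic
#' attack. Conventions vary in the literature; this one is used consistently
#' throughout the package. When the charge sets obey their sum rules the
#' columns obey `sum(f_plus) = sum(f_minus) = 1` and `sum(dual) = 0`.
#'
#' @param record An `esr` object whose `atoms` carry all three charge sets.
#' @return A `local_site_table` data frame with columns `index`, `element`,
#'   `f_plus`, `f_minus`, `f_zero`, `dual`, plus attributes `charge_scheme`
#'   and `molecule_id`.
#' @export
#' @examples
#' rec <- generate_synthetic_record(seed = 7, n_atoms = 20)
#' colSums(condensed_fukui(rec)[, c("f_plus", "f_minus", "dual")])
condensed_fukui <- function(record) {
  atoms <- record$atoms
  if (is.null(atoms)) {
    stop("record '", record$molecule_id, "' carries no per-atom data",
         call. = FALSE)
  }
  for (sp in c("q_neutral", "q_cation", "q_anion")) {
    if (is.null(atoms[[sp]])) {
      stop("missing charge set '", sp, "' in record '",
           record$molecule_id, "'", call. = FALSE)
    }
  }
  f_plus <- atoms$q_neutral - atoms$q_anion
  f_minus <- atoms$q_cation - atoms$q_neutral
  out <- data.frame(
    index = atoms$index,
    element = atoms$element,
    f_plus = f_plus,
    f_minus = f_minus,
    f_zero = (f_plus + f_minus) / 2,
    dual = f_plus - f_minus,
    stringsAsFactors = FALSE
  )
  .as_site_table(out, record)
}

#' Condensed Parr functions and their difference
#'
#' The Parr functions are the atomic spin populations of the radical ions of
#' the parent molecule: the nucleophilic Parr function `p_minus` is the spin
#' population of the radical cation, the electrophilic Parr function
#' `p_plus` that of the radical anion. Their difference
#' `parr_diff = p_plus - p_minus` is a site-resolved descriptor analogous to
#' the dual descriptor, with the same sign convention (positive: favored for
#' nucleophilic attack). Each spin set sums to 1 for doublet ions, so
#' `sum(parr_diff) = 0`.
#'
#' @param record An `esr` object whose `atoms` carry `spin_cation` and/or
#'   `spin_anion`; a partial table is returned when only one is present.
#' @return A `local_site_table` data frame with columns `index`, `element`,
#'   `p_minus`, `p_plus`, `parr_diff` (`NA` columns when the corresponding
#'   spin set is absent).
#' @export
parr_functions <- function(record) {
  atoms <- record$atoms
  if (is.null(atoms) ||
      (is.null(atoms$spin_cation) && is.null(atoms$spin_anion))) {
    stop("record '", record$molecule_id,
         "' carries no atomic spin populations", call. = FALSE)
  }
  p_minus <- if (is.null(atoms$spin_cation)) NA_real_ else atoms$spin_cation
  p_plus <- if (is.null(atoms$spin_anion)) NA_real_ else atoms$spin_anion
  out <- data.frame(
    index = atoms$index,
    element = atoms$element,
    p_minus = p_minus,
    p_plus = p_plus,
    parr_diff = p_plus - p_minus,
    stringsAsFactors = FALSE
  )
  .as_site_table(out, record)
}

#' Full local-reactivity site table
#'
#' Merges [condensed_fukui()] and [parr_functions()] into the standard
#' per-atom report (atom, element, f-, f+, f0, dual, P-, P+, parr_diff),
#' keeping whichever halves the record supports.
#'
#' @param record An `esr` object with per-atom data.
#' @return A `local_site_table` data frame.
#' @export
local_site_table <- function(record) {
  fuk <- tryCatch(condensed_fukui(record), error = function(e) NULL)
  par <- tryCatch(parr_functions(record), error = function(e) NULL)
  if (is.null(fuk) && is.null(par)) {
    stop("record '", record$molecule_id,
         "' supports neither Fukui nor Parr condensation", call. = FALSE)
  }
  out <- if (is.null(fuk)) par else if (is.null(par)) fuk else
    merge(fuk, par[, setdiff(names(par), "element")], by = "index",
          sort = TRUE)
  .as_site_table(out[order(out$index), , drop = FALSE], record)
}

.as_site_table <- function(df, record) {
  rownames(df) <- NULL
  attr(df, "molecule_id") <- record$molecule_id
  attr(df, "charge_scheme") <- record$charge_scheme
  attr(df, "n_atoms") <- nrow(df)
  class(df) <- c("local_site_table", "data.frame")
  df
}

#' Rank reactive sites by a local descriptor
#'
#' Returns the top-`k` atoms by descending descriptor value; for the dual
#' descriptor and `parr_diff` that means the sites most susceptible to
#' nucleophilic attack (rank on their negation to get electrophilic sites).
#' Ties are broken by ascending atom index.
#'
#' @param table A `local_site_table`.
#' @param descriptor Column to rank on, e.g. `"f_plus"`, `"f_minus"`,
#'   `"dual"`, `"p_plus"`.
#' @param k Number of sites to return; values above the number of available
#'   atoms are truncated with a warning.
#' @param heavy_only Exclude hydrogens before ranking.
#' @return The selected rows of `table`, ranked, with a `rank` column.
#' @export
rank_sites <- function(table, descriptor, k = 3L, heavy_only = FALSE) {
  if (!descriptor %in% names(table)) {
    stop("descriptor column '", descriptor, "' not present", call. = FALSE)
  }
  stopifnot(k >= 1L)
  tab <- as.data.frame(table)
  if (heavy_only) tab <- tab[tab$element != "H", , drop = FALSE]
  if (k > nrow(tab)) {
    warning("k = ", k, " exceeds the ", nrow(tab),
            " available sites; returning all of them")
    k <- nrow(tab)
  }
  ord <- order(-tab[[descriptor]], tab$index)
  out <- tab[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Agreement between Fukui- and Parr-based site predictions
#'
#' Compares the reactive sites predicted by the Fukui functions with those
#' predicted by the Parr functions, per attack channel: the nucleophilic
#' channel pairs `f_plus` with `p_plus`, the electrophilic channel `f_minus`
#' with `p_minus`. Reports the top-`k` overlap fraction of each channel and
#' the concentration ratio max(Parr)/max(Fukui), which exceeds 1 when the
#' Parr functions are the sharper (more compact) of the two site maps.
#'
#' @param table A `local_site_table` carrying both Fukui and Parr columns.
#' @param k Number of top sites compared per channel.
#' @return A list with `k`, `overlap_plus`, `overlap_minus` (fractions in
#'   `[0, 1]`), `concentration_plus`, `concentration_minus`.
#' @export
compare_fukui_parr <- function(table, k = 3L) {
  need <- c("f_plus", "f_minus", "p_plus", "p_minus")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0 || anyNA(table[, need])) {
    stop("comparison needs complete Fukui and Parr columns; missing or NA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  top <- function(col) rank_sites(table, col, k = k)$index
  overlap <- function(a, b) length(intersect(a, b)) / length(a)
  list(
    k = k,
    overlap_plus = overlap(top("f_plus"), top("p_plus")),
    overlap_minus = overlap(top("f_minus"), top("p_minus")),
    concentration_plus = max(table$p_plus) / max(table$f_plus),
    concentration_minus = max(table$p_minus) / max(table$f_minus)
  )
}

#' Export a local site table to CSV
#'
#' Writes the per-atom table in the conventional appendix shape
#' (atom, element, f-, f+, f0, dual, P-, P+, parr_diff), full precision.
#'
#' @param table A `local_site_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
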