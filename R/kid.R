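#' Koopmans-in-DFT (KID) compliance descriptors
#'
#' Quantifies how closely a calculation obeys the generalized Kohn-Sham
#' analogue of Koopmans' theorem, under which the HOMO energy equals minus
#' the vertical ionization potential and the radical anion's SOMO matches
#' the neutral's LUMO. Four non-negative descriptors (in eV) are computed:
#'
#' * `j_i  = |eps_HOMO + E(N-1) - E(N)|` — HOMO vs ionization potential;
#' * `j_a  = |eps_LUMO + E(N) - E(N+1)|` — LUMO vs electron affinity;
#' * `j_hl = sqrt(j_i^2 + j_a^2)` — their quadrature combination;
#' * `delta_sl = |eps_SOMO(anion) - eps_LUMO(neutral)|`.
#'
#' Values near zero indicate a Koopmans-compliant functional, justifying the
#' orbital-energy route to the global reactivity descriptors
#' ([compute_global()]). Partial input yields a partial report: descriptors
#' whose inputs are absent come back `NA` and are ignored by the compliance
#' verdict.
#'
#' @param record An `esr` object; any energy unit (converted internally).
#' @param tolerance Per-descriptor compliance threshold in eV. The verdict
#'   `compliant` is `TRUE` iff every available descriptor is <= `tolerance`.
#' @return A `kid_report`: list with `j_i`, `j_a`, `j_hl`, `delta_sl`
#'   (eV, `NA` when not computable), `compliant`, and `tolerance_used`.
#' @export
#' @examples
#' rec <- generate_synthetic_record(seed = 1, n_atoms = 5, delta_max = 0)
#' compute_kid(rec)$j_hl   # 0: Koopmans-exact by construction
compute_kid <- function(record, tolerance = 0.10) {
  stopifnot(is.numeric(tolerance), length(tolerance) == 1L, tolerance >= 0)
  rec <- .as_ev(record)
  has_fd <- !is.null(rec$e_n) && !is.null(rec$e_nm1) && !is.null(rec$e_np1)
  has_sl <- !is.null(rec$eps_somo_anion)
  if (!has_fd && !has_sl) {
    stop("no KID input available: record '", rec$molecule_id,
         "' carries neither total energies nor an anion SOMO energy",
         call. = FALSE)
  }
  j_i <- j_a <- j_hl <- delta_sl <- NA_real_
  if (has_fd) {
    j_i <- abs(rec$eps_homo + rec$e_nm1 - rec$e_n)
    j_a <- abs(rec$eps_lumo + rec$e_n - rec$e_np1)
    j_hl <- sqrt(j_i^2 + j_a^2)
  }
  if (has_sl) delta_sl <- abs(rec$eps_somo_anion - rec$eps_lumo)
  vals <- c(j_i = j_i, j_a = j_a, j_hl = j_hl, delta_sl = delta_sl)
  structure(list(
    molecule_id = rec$molecule_id,
    j_i = j_i, j_a = j_a, j_hl = j_hl, delta_sl = delta_sl,
    compliant = all(vals[!is.na(vals)] <= tolerance),
    tolerance_used = tolerance
  ), class = "kid_report")
}

#' @export
print.kid_report <- function(x, ...) {
  cat("<KID compliance report> ", x$molecule_id, "\n", sep = "")
  cat(sprintf("  J_I = %s, J_A = %s, J_HL = %s, dSL = %s eV\n",
              .fmt_na(x$j_i), .fmt_na(x$j_a), .fmt_na(x$j_hl),
              .fmt_na(x$delta_sl)))
  cat(sprintf("  %s (tolerance %.3g eV per descriptor)\n",
              if (x$compliant) "Koopmans-compliant" else "NOT compliant",
              x$tolerance_used))
  invisible(x)
}

.fmt_na <- function(x, digits = 4) {
  if (is.na(x)) "NA" else formatC(x, digits = digits, format = "f")
}

#' Tabulate KID descriptors for a set of records
#'
#' One row per record, in the conventional report shape: frontier-orbital
#' energies, anion SOMO, HOMO-LUMO gap, then the four KID descriptors and
#' the compliance verdict. Energies are reported in eV.
#'
#' @param records A list of `esr` objects (or a single record).
#' @param tolerance Passed on to [compute_kid()].
#' @return A data frame with columns `molecule_id`, `homo`, `lumo`, `somo`,
#'   `gap`, `j_i`, `j_a`, `j_hl`, `delta_sl`, `compliant`.
#' @export
kid_table <- function(records, tolerance = 0.10) {
  records <- .as_record_list(records)
  rows <- lapply(records, function(r) {
    rec <- .as_ev(r)
    k <- compute_kid(rec, tolerance = tolerance)
    data.frame(
      molecule_id = rec$molecule_id,
      homo = rec$eps_homo, lumo = rec$eps_lumo,
      somo = if (is.null(rec$eps_somo_anion)) NA_real_ else rec$eps_somo_anion,
      gap = rec$eps_lumo - rec$eps_homo,
      j_i = k$j_i, j_a = k$j_a, j_hl = k$j_hl, delta_sl = k$delta_sl,
      compliant = k$compliant,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.as_record_list <- function(records) {
  if (inherits(records, "esr")) list(records) else records
}
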