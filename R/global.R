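#' Default HOMO energy of the tetracyanoethylene reference
#'
#' The nucleophilicity index is the HOMO energy measured relative to that of
#' tetracyanoethylene (TCE), the least nucleophilic reference of the Domingo
#' scale, at the same level of theory. This shipped default was calibrated
#' from the packaged theopapuamide benchmark (HOMO and nucleophilicity of
#' peptide A), not computed ab initio; supply your own value when working at
#' a different level of theory.
#'
#' @format A length-one numeric, in eV.
#' @export
tce_homo_default <- -9.1212

#' Global conceptual-DFT reactivity descriptors
#'
#' Computes the standard global descriptors from a record, in one of two
#' modes. In `"orbital"` mode (the default, appropriate for a
#' Koopmans-compliant functional as verified by [compute_kid()]) the
#' vertical ionization potential and electron affinity are taken from the
#' frontier orbitals, `I = -eps_HOMO`, `A = -eps_LUMO`; in
#' `"finite_difference"` mode they come from total-energy differences,
#' `I = E(N-1) - E(N)`, `A = E(N) - E(N+1)`. Either way (all in eV):
#'
#' * electronegativity `chi = (I + A) / 2` (chemical potential `mu = -chi`);
#' * global hardness `eta = I - A`; softness `S = 1/eta` (eV^-1);
#' * electrophilicity `omega = chi^2 / (2 eta)`;
#' * electrodonating power `omega_minus = (3I + A)^2 / (16 eta)`;
#' * electroaccepting power `omega_plus = (I + 3A)^2 / (16 eta)`;
#' * net electrophilicity `= omega_plus + omega_minus`;
#' * nucleophilicity `N = eps_HOMO - eps_HOMO(TCE)` (orbital mode only).
#'
#' @param record An `esr` object; any energy unit (converted internally).
#' @param mode `"orbital"` or `"finite_difference"`.
#' @param tce_homo_ref HOMO energy (eV) of the tetracyanoethylene reference,
#'   or `NULL` to omit the nucleophilicity index. Defaults to
#'   [tce_homo_default]; only used in orbital mode.
#' @return A `global_descriptors` list with fields `chi`, `mu`, `eta`,
#'   `softness`, `omega`, `omega_minus`, `omega_plus`,
#'   `net_electrophilicity`, `nucleophilicity_n` (`NA` when unavailable),
#'   and `mode`.
#' @export
#' @examples
#' rec <- electronic_structure_record("A", eps_homo = -6.3114,
#'                                    eps_lumo = -0.8210)
#' g <- compute_global(rec)
#' round(c(g$chi, g$eta, g$omega), 4)   # 3.5662 5.4904 1.1582
compute_global <- function(record,
                           mode = c("orbital", "finite_difference"),
                           tce_homo_ref = tce_homo_default) {
  mode <- match.arg(mode)
  rec <- .as_ev(record)
  if (mode == "orbital") {
    i <- -rec$eps_homo
    a <- -rec$eps_lumo
  } else {
    if (is.null(rec$e_n) || is.null(rec$e_nm1) || is.null(rec$e_np1)) {
      stop("finite-difference mode requires the total energies ",
           "e_n, e_nm1, e_np1 (record '", rec$molecule_id, "')",
           call. = FALSE)
    }
    i <- rec$e_nm1 - rec$e_n
    a <- rec$e_n - rec$e_np1
  }
  eta <- i - a
  if (eta <= 0) {
    stop("unphysical ordering: hardness I - A = ", format(eta),
         " <= 0 for record '", rec$molecule_id, "'", call. = FALSE)
  }
  chi <- (i + a) / 2
  nuc <- if (mode == "orbital" && !is.null(tce_homo_ref)) {
    rec$eps_homo - tce_homo_ref
  } else NA_real_
  structure(list(
    molecule_id = rec$molecule_id,
    chi = chi,
    mu = -chi,
    eta = eta,
    softness = 1 / eta,
    omega = chi^2 / (2 * eta),
    omega_minus = (3 * i + a)^2 / (16 * eta),
    omega_plus = (i + 3 * a)^2 / (16 * eta),
    net_electrophilicity = (3 * i + a)^2 / (16 * eta) +
      (i + 3 * a)^2 / (16 * eta),
    nucleophilicity_n = nuc,
    mode = mode
  ), class = "global_descriptors")
}

#' @export
print.global_descriptors <- function(x, ...) {
  cat("<global reactivity descriptors> ", x$molecule_id,
      " [", x$mode, " mode]\n", sep = "")
  cat(sprintf("  chi = %.4f  eta = %.4f  S = %.4f  omega = %.4f (eV; S eV^-1)\n",
              x$chi, x$eta, x$softness, x$omega))
  cat(sprintf("  omega- = %.4f  omega+ = %.4f  net = %.4f  N = %s\n",
              x$omega_minus, x$omega_plus, x$net_electrophilicity,
              .fmt_na(x$nucleophilicity_n)))
  invisible(x)
}

#' Classify a molecule on the Domingo nucleophilicity scale
#'
#' Molecules with a nucleophilicity index above 3.0 eV count as strong
#' nucleophiles; between 2.0 and 3.0 eV as moderate; below as marginal.
#' Both boundaries are configurable.
#'
#' @param n Nucleophilicity index in eV (vectorised).
#' @param boundaries Length-two increasing numeric: the marginal/moderate
#'   and moderate/strong cut points (eV).
#' @return Character vector in `{"marginal", "moderate", "strong"}`.
#' @export
#' @examples
#' classify_nucleophile(c(1.0, 2.8098, 3.2174))
classify_nucleophile <- function(n, boundaries = c(2.0, 3.0)) {
  stopifnot(is.numeric(n), all(is.finite(n)),
            length(boundaries) == 2L, boundaries[1] < boundaries[2])
  ifelse(n > boundaries[2], "strong",
         ifelse(n > boundaries[1], "moderate", "marginal"))
}

#' Tabulate global descriptors for a set of records
#'
#' One row per record in the conventional report shape (all eV except the
#' softness, eV^-1).
#'
#' @param records A list of `esr` objects (or a single record).
#' @inheritParams compute_global
#' @return A data frame with columns `molecule_id`, `chi`, `eta`, `omega`,
#'   `softness`, `nucleophilicity_n`, `omega_minus`, `omega_plus`,
#'   `net_electrophilicity`.
#' @export
global_table <- function(records, mode = c("orbital", "finite_difference"),
                         tce_homo_ref = tce_homo_default) {
  mode <- match.arg(mode)
  records <- .as_record_list(records)
  rows <- lapply(records, function(r) {
    g <- compute_global(r, mode = mode, tce_homo_ref = tce_homo_ref)
    data.frame(
      molecule_id = g$molecule_id,
      chi = g$chi, eta = g$eta, omega = g$omega, softness = g$softness,
      nucleophilicity_n = g$nucleophilicity_n,
      omega_minus = g$omega_minus, omega_plus = g$omega_plus,
      net_electrophilicity = g$net_electrophilicity,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
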