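#' Default bioavailability-radar axis ranges
#'
#' The six-axis radar summarises oral drug-likeness: each physicochemical
#' property has an optimal interval, and a candidate whose profile stays
#' inside all six is radar-clean. The shipped defaults are the widely used
#' published bounds; all are configurable.
#'
#' @return A data frame with columns `axis`, `property`, `lower`, `upper`:
#'   LIPO (logP, -0.7..5.0), SIZE (molecular weight, 150..500 g/mol),
#'   POLAR (TPSA, 20..130 A^2), INSOLU (logS, -6..0), INSATU (fraction of
#'   sp3 carbons, 0.25..1.0), FLEX (rotatable bonds, 0..9).
#' @export
default_radar_ranges <- function() {
  data.frame(
    axis = c("LIPO", "SIZE", "POLAR", "INSOLU", "INSATU", "FLEX"),
    property = c("logp_estimate", "molecular_weight", "tpsa",
                 "logs_estimate", "fraction_csp3", "rotatable_bonds"),
    lower = c(-0.7, 150, 20, -6, 0.25, 0),
    upper = c(5.0, 500, 130, 0, 1.0, 9),
    stringsAsFactors = FALSE
  )
}

# SMARTS patterns condensed to counts per molecule. The rotatable-bond
# pattern is the classic Daylight/Veber definition (single, acyclic,
# non-terminal, not adjacent to a triple bond; amides counted); OpenBabel
# reports each bond match twice (once per direction).
.profile_smarts <- c(
  rotatable = "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]",
  csp3 = "[CX4]",
  carbon = "[#6]",
  aromatic = "[a]",
  heavy = "[!#1]"
)

#' Physicochemical drug-likeness profile from SMILES
#'
#' Parses a SMILES string (via OpenBabel) and computes the descriptors that
#' feed the bioavailability radar and the rule-based drug-likeness flags:
#' molecular weight, an open logP estimate (OpenBabel's atom-contribution
#' logP, recorded by name -- deliberately not any proprietary estimator),
#' topological polar surface area, Lipinski hydrogen-bond donor and
#' acceptor (N+O) counts, molar refractivity, rotatable-bond count,
#' fraction of sp3 carbons, aromatic heavy-atom proportion, and an ESOL
#' topological water-solubility estimate
#' `logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`
#' (Delaney's method; AP is the aromatic proportion). Rule flags:
#' `lipinski_violations` counts broken rules among MW > 500, logP > 5,
#' HBD > 5, HBA > 10; `veber_pass` is TRUE iff rotatable bonds <= 10 and
#' TPSA <= 140 A^2.
#'
#' The profile depends only on the molecular graph, so equivalent SMILES of
#' the same molecule give identical profiles.
#'
#' @param smiles A single SMILES string.
#' @return A `drug_profile` list with fields `smiles`, `canonical_smiles`,
#'   `formula`, `molecular_weight`, `logp_estimate`, `logp_method`, `tpsa`,
#'   `hbd`, `hba`, `molar_refractivity`, `rotatable_bonds`, `heavy_atoms`,
#'   `fraction_csp3`, `aromatic_proportion`, `logs_estimate`, `logs_method`,
#'   `lipinski_violations`, `veber_pass`.
#' @export
#' @examples
#' \donttest{
#' p <- compute_profile("CCO")
#' c(p$hbd, p$hba, p$rotatable_bonds)   # 1 1 0
#' }
compute_profile <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trimws(smiles))) {
    stop("SMILES parse error: empty input", call. = FALSE)
  }
  parsed <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
      counts <- vapply(.profile_smarts, function(p) {
        ChemmineOB::smartsSearch_OB(list(mol), p, uniqueMatches = FALSE)
      }, numeric(1))
      list(prop = ChemmineOB::prop_OB(mol), counts = counts)
    }),
    error = function(e) {
      stop("SMILES parse error in '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(parsed) == 0L) {
    stop("SMILES parse error in '", smiles, "': no molecule read",
         call. = FALSE)
  }
  prop <- parsed[[1L]]$prop
  counts <- parsed[[1L]]$counts
  if (!nzchar(prop$formula) || counts[["heavy"]] < 1) {
    stop("SMILES parse error in '", smiles, "': no atoms parsed",
         call. = FALSE)
  }

  mw <- prop$MW
  logp <- prop$logP
  rotatable <- counts[["rotatable"]] / 2          # OB counts both directions
  n_carbon <- counts[["carbon"]]
  fraction_csp3 <- if (n_carbon > 0) counts[["csp3"]] / n_carbon else 0
  aromatic_prop <- counts[["aromatic"]] / counts[["heavy"]]
  logs <- 0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rotatable -
    0.74 * aromatic_prop
  hbd <- prop$HBD
  hba <- prop$HBA1                                # Lipinski N+O count

  structure(list(
    smiles = smiles,
    canonical_smiles = prop$cansmi,
    formula = prop$formula,
    molecular_weight = mw,
    logp_estimate = logp,
    logp_method = "OpenBabel atom-contribution logP",
    tpsa = prop$TPSA,
    hbd = hbd,
    hba = hba,
    molar_refractivity = prop$MR,
    rotatable_bonds = rotatable,
    heavy_atoms = counts[["heavy"]],
    fraction_csp3 = fraction_csp3,
    aromatic_proportion = aromatic_prop,
    logs_estimate = logs,
    logs_method = "ESOL (Delaney 2004)",
    lipinski_violations = sum(mw > 500, logp > 5, hbd > 5, hba > 10),
    veber_pass = rotatable <= 10 && prop$TPSA <= 140
  ), class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("<drug-likeness profile> ", x$canonical_smiles,
      " (", x$formula, ")\n", sep = "")
  cat(sprintf("  MW %.2f  logP %.2f (%s)  TPSA %.2f A^2  MR %.2f\n",
              x$molecular_weight, x$logp_estimate, x$logp_method, x$tpsa,
              x$molar_refractivity))
  cat(sprintf("  HBD %d  HBA %d  rotatable %d  fCsp3 %.3f  logS %.2f (%s)\n",
              as.integer(x$hbd), as.integer(x$hba),
              as.integer(x$rotatable_bonds), x$fraction_csp3,
              x$logs_estimate, x$logs_method))
  cat(sprintf("  Lipinski violations: %d; Veber: %s\n",
              x$lipinski_violations, if (x$veber_pass) "pass" else "fail"))
  invisible(x)
}

#' Bioavailability-radar axes for a profile
#'
#' Maps a [compute_profile()] result onto the six radar axes and flags each
#' value against its configured optimal interval. Intervals are closed:
#' a value exactly on a bound is in range.
#'
#' @param profile A `drug_profile`.
#' @param ranges Axis ranges as produced by [default_radar_ranges()].
#' @return A data frame with columns `axis`, `value`, `lower`, `upper`,
#'   `in_range`, one row per axis (LIPO, SIZE, POLAR, INSOLU, INSATU, FLEX).
#' @export
radar_axes <- function(profile, ranges = default_radar_ranges()) {
  stopifnot(inherits(profile, "drug_profile"),
            all(c("axis", "property", "lower", "upper") %in% names(ranges)))
  value <- vapply(ranges$property, function(p) as.numeric(profile[[p]]),
                  numeric(1))
  data.frame(
    axis = ranges$axis,
    value = unname(value),
    lower = ranges$lower,
    upper = ranges$upper,
    in_range = unname(value >= ranges$lower & value <= ranges$upper),
    stringsAsFactors = FALSE
  )
}

#' Tabulate drug-likeness profiles for several molecules
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional molecule labels (defaults to the SMILES themselves).
#' @return A data frame with one row per molecule and the scalar fields of
#'   [compute_profile()] as columns.
#' @export
profile_table <- function(smiles, ids = smiles) {
  stopifnot(length(smiles) == length(ids))
  rows <- Map(function(s, id) {
    p <- compute_profile(s)
    data.frame(
      molecule_id = id, smiles = s,
      molecular_weight = p$molecular_weight,
      logp_estimate = p$logp_estimate, tpsa = p$tpsa,
      hbd = p$hbd, hba = p$hba,
      rotatable_bonds = p$rotatable_bonds,
      fraction_csp3 = p$fraction_csp3,
      molar_refractivity = p$molar_refractivity,
      logs_estimate = p$logs_estimate,
      lipinski_violations = p$lipinski_violations,
      veber_pass = p$veber_pass,
      stringsAsFactors = FALSE
    )
  }, smiles, ids)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
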