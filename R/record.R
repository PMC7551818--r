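#' Energy-unit conversion constant
#'
#' One hartree expressed in electron-volts. Pinned to a fixed value so that
#' converted records are bit-reproducible across platforms.
#'
#' @format A length-one numeric.
#' @export
ev_per_hartree <- 27.211386

# energy-carrying scalar fields of a record, scaled together on unit conversion
.energy_fields <- c("eps_homo", "eps_lumo", "eps_somo_anion",
                    "e_n", "e_nm1", "e_np1")

#' Construct an electronic-structure record
#'
#' An electronic-structure record is the single input consumed by every
#' reactivity computation in the package: one molecule's frontier-orbital
#' energies, optionally the ground-state total energies of the N, N-1 and
#' N+1 electron species, and optionally per-atom partial charges and spin
#' populations. Records typically summarise a converged single-point
#' calculation; this package consumes such summaries, it never runs
#' electronic-structure calculations itself.
#'
#' @param molecule_id Text label for the molecule.
#' @param eps_homo,eps_lumo HOMO and LUMO energies of the neutral
#'   (N-electron) species, in the unit given by `unit`.
#' @param eps_somo_anion HOMO (SOMO) energy of the radical anion
#'   (N+1-electron species), optional.
#' @param e_n,e_nm1,e_np1 Ground-state total energies of the N, N-1 and N+1
#'   electron species. Optional, but must be supplied (or omitted) as a group.
#' @param atoms Optional data frame of per-atom data with columns `index`
#'   (1-based, contiguous), `element`, and optionally `q_neutral`,
#'   `q_cation`, `q_anion` (partial charges of the three species, in e,
#'   all three or none) and `spin_cation`, `spin_anion` (atomic spin
#'   populations of the radical ions).
#' @param unit Energy unit of every energy field: `"eV"` or `"hartree"`.
#' @param charge Integer total charge of the neutral-species calculation.
#' @param multiplicity Integer spin multiplicity of the neutral species.
#' @param method Free-text metadata (functional, basis set, solvent model);
#'   informational only.
#' @param charge_scheme Free-text name of the population-analysis scheme
#'   behind the atomic charges and spins. Recorded as metadata and never
#'   interpreted.
#' @param extra Named list of additional metadata preserved on round trips.
#' @param validate Validate the record before returning it (default `TRUE`).
#'
#' @return An object of class `esr` (a validated list).
#' @seealso [load_record()], [write_record()], [validate_record()],
#'   [generate_synthetic_record()]
#' @export
#' @examples
#' rec <- electronic_structure_record("mol", eps_homo = -6.3, eps_lumo = -0.8)
#' rec$eps_homo
electronic_structure_record <- function(molecule_id,
                                        eps_homo, eps_lumo,
                                        eps_somo_anion = NULL,
                                        e_n = NULL, e_nm1 = NULL, e_np1 = NULL,
                                        atoms = NULL,
                                        unit = "eV",
                                        charge = 0L, multiplicity = 1L,
                                        method = "",
                                        charge_scheme = "",
                                        extra = list(),
                                        validate = TRUE) {
  rec <- structure(list(
    schema_version = "1.0",
    molecule_id = as.character(molecule_id),
    method = as.character(method),
    charge = as.integer(charge),
    multiplicity = as.integer(multiplicity),
    unit = unit,
    eps_homo = as.numeric(eps_homo),
    eps_lumo = as.numeric(eps_lumo),
    eps_somo_anion = if (!is.null(eps_somo_anion)) as.numeric(eps_somo_anion),
    e_n = if (!is.null(e_n)) as.numeric(e_n),
    e_nm1 = if (!is.null(e_nm1)) as.numeric(e_nm1),
    e_np1 = if (!is.null(e_np1)) as.numeric(e_np1),
    charge_scheme = as.character(charge_scheme),
    atoms = atoms,
    extra = extra
  ), class = "esr")
  if (validate) validate_record(rec)
  rec
}

#' Validate an electronic-structure record
#'
#' Checks the structural schema and the physical invariants of a record:
#' a strict HOMO < LUMO ordering, the all-or-none grouping of the total
#' energies and of the three charge sets, contiguous 1-based atom indexing,
#' and the population sum rules. For a record of total charge Q the partial
#' charges must satisfy sum(q_neutral) = Q, sum(q_cation) = Q+1 and
#' sum(q_anion) = Q-1, and the spin populations of the doublet radical ions
#' of a closed-shell parent must each sum to 1, all within `sum_tolerance`.
#'
#' @param record An `esr` object (or bare list in record shape).
#' @param sum_tolerance Absolute tolerance, in e, for every population sum
#'   rule. Population analyses carry rounding, hence the permissive default.
#' @return The record, invisibly, if valid. Otherwise an error naming the
#'   violated field or sum rule.
#' @export
validate_record <- function(record, sum_tolerance = 1e-3) {
  fail <- function(...) stop("invalid record: ", ..., call. = FALSE)
  for (f in c("molecule_id", "unit", "eps_homo", "eps_lumo", "charge",
              "multiplicity")) {
    if (is.null(record[[f]])) fail("missing required field '", f, "'")
  }
  if (!record$unit %in% c("eV", "hartree")) {
    fail("unknown unit tag '", record$unit, "' (expected 'eV' or 'hartree')")
  }
  for (f in .energy_fields) {
    v <- record[[f]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v))) {
      fail("field '", f, "' must be a finite numeric scalar")
    }
  }
  if (record$eps_homo >= record$eps_lumo) {
    fail("eps_homo must lie strictly below eps_lumo (got ",
         record$eps_homo, " >= ", record$eps_lumo, ")")
  }
  en_present <- !vapply(record[c("e_n", "e_nm1", "e_np1")], is.null, logical(1))
  if (any(en_present) && !all(en_present)) {
    fail("total energies e_n, e_nm1, e_np1 must be supplied as a group; ",
         "missing: ", paste(c("e_n", "e_nm1", "e_np1")[!en_present],
                            collapse = ", "))
  }
  if (!is.null(record$atoms)) {
    .validate_atoms(record$atoms, record$charge, sum_tolerance, fail)
  }
  invisible(record)
}

.validate_atoms <- function(atoms, charge, tol, fail) {
  if (!is.data.frame(atoms)) fail("atoms must be a data frame")
  if (is.null(atoms$index) || is.null(atoms$element)) {
    fail("atoms must carry 'index' and 'element' columns")
  }
  n <- nrow(atoms)
  if (!identical(as.integer(atoms$index), seq_len(n))) {
    fail("atom indices must run 1..", n, " contiguously")
  }
  qcols <- c("q_neutral", "q_cation", "q_anion")
  q_present <- qcols %in% names(atoms)
  if (any(q_present) && !all(q_present)) {
    fail("partial charges must be supplied for all three species; missing: ",
         paste(qcols[!q_present], collapse = ", "))
  }
  check_sum <- function(x, target, label) {
    if (abs(sum(x) - target) > tol) {
      fail("sum rule broken: sum(", label, ") = ", format(sum(x)),
           " but must equal ", target, " within ", tol, " e")
    }
  }
  if (all(q_present)) {
    check_sum(atoms$q_neutral, charge, "q_neutral")
    check_sum(atoms$q_cation, charge + 1, "q_cation")
    check_sum(atoms$q_anion, charge - 1, "q_anion")
  }
  if (!is.null(atoms$spin_cation)) check_sum(atoms$spin_cation, 1, "spin_cation")
  if (!is.null(atoms$spin_anion)) check_sum(atoms$spin_anion, 1, "spin_anion")
  invisible(atoms)
}

#' Read an electronic-structure record from JSON
#'
#' Reads the package's flat JSON record format (one molecule per document,
#' explicit `schema_version`), validates it, and preserves any unknown
#' top-level fields as metadata under `$extra`.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @param sum_tolerance Passed on to [validate_record()].
#' @return A validated `esr` object.
#' @export
#' @examples
#' path <- system.file("extdata", "theopapuamide_A.json", package = "cdftkit")
#' rec <- load_record(path)
#' rec$eps_homo
load_record <- function(source, sum_tolerance = 1e-3) {
  raw <- tryCatch(
    jsonlite::fromJSON(source, simplifyDataFrame = TRUE),
    error = function(e) stop("record parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.list(raw)) stop("record parse error: top level must be an object",
                          call. = FALSE)
  known <- c("schema_version", "molecule_id", "method", "charge",
             "multiplicity", "unit", "eps_homo", "eps_lumo", "eps_somo_anion",
             "e_n", "e_nm1", "e_np1", "charge_scheme", "atoms", "extra")
  for (f in c("molecule_id", "unit", "eps_homo", "eps_lumo")) {
    if (is.null(raw[[f]])) {
      stop("record parse error: missing required field '", f, "'",
           call. = FALSE)
    }
  }
  atoms <- raw$atoms
  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    atoms$index <- as.integer(atoms$index)
  }
  extra <- c(raw[setdiff(names(raw), known)],
             if (is.list(raw$extra)) raw$extra)
  rec <- electronic_structure_record(
    molecule_id = raw$molecule_id,
    eps_homo = raw$eps_homo, eps_lumo = raw$eps_lumo,
    eps_somo_anion = raw$eps_somo_anion,
    e_n = raw$e_n, e_nm1 = raw$e_nm1, e_np1 = raw$e_np1,
    atoms = atoms,
    unit = raw$unit,
    charge = if (is.null(raw$charge)) 0L else raw$charge,
    multiplicity = if (is.null(raw$multiplicity)) 1L else raw$multiplicity,
    method = if (is.null(raw$method)) "" else raw$method,
    charge_scheme = if (is.null(raw$charge_scheme)) "" else raw$charge_scheme,
    extra = extra,
    validate = FALSE
  )
  validate_record(rec, sum_tolerance = sum_tolerance)
  rec
}

#' Write an electronic-structure record to JSON
#'
#' Inverse of [load_record()]: full double precision is retained so a
#' write/read round trip is lossless.
#'
#' @param record An `esr` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  out <- record[!vapply(record, is.null, logical(1))]
  extra <- out$extra
  out$extra <- NULL
  out <- c(out, extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Convert the energy unit of a record
#'
#' Scales every energy field (orbital energies and total energies) by the
#' pinned hartree/eV factor [ev_per_hartree]; atomic charges and spin
#' populations are dimensionless and untouched. Converting to the record's
#' current unit is the identity.
#'
#' @param record An `esr` object.
#' @param target `"eV"` or `"hartree"`.
#' @return The converted record.
#' @export
convert_units <- function(record, target = c("eV", "hartree")) {
  target <- match.arg(target)
  if (!record$unit %in% c("eV", "hartree")) {
    stop("unknown unit tag '", record$unit, "'", call. = FALSE)
  }
  if (identical(record$unit, target)) return(record)
  factor <- if (target == "eV") ev_per_hartree else 1 / ev_per_hartree
  for (f in .energy_fields) {
    if (!is.null(record[[f]])) record[[f]] <- record[[f]] * factor
  }
  record$unit <- target
  record
}

# internal: descriptor computations always work in eV
.as_ev <- function(record) convert_units(record, "eV")

#' Generate a synthetic electronic-structure record
#'
#' Produces a reproducible, fully valid record for testing and simulation.
#' The construction makes the Koopmans-compliance error controllable: with
#' total energies requested, `E(N-1) - E(N) = -eps_homo + dI` and
#' `E(N) - E(N+1) = -eps_lumo + dA`, with `dI`, `dA` (and the SOMO offset)
#' drawn uniformly from `[-delta_max, delta_max]` eV, so the downstream KID
#' descriptors equal `|dI|`, `|dA|` and their quadrature sum exactly;
#' `delta_max = 0` yields a Koopmans-exact record. Per-atom charge sets are
#' built from normalised Fukui weights so every population sum rule holds
#' exactly, and the spin populations are sharpened powers of those weights
#' (renormalised), emulating the empirically more compact Parr functions
#' while preserving the site ranking.
#'
#' @param seed Integer seed; the same seed yields an identical record. The
#'   caller's RNG state is left untouched.
#' @param n_atoms Number of atoms (>= 1) when `with_atoms`.
#' @param with_energies Include total energies of the three species and the
#'   anion SOMO.
#' @param with_atoms Include per-atom charges and spin populations.
#' @param delta_max Half-width, in eV, of the uniform Koopmans perturbation.
#' @param parr_power Exponent of the sharpening transform mapping Fukui
#'   weights to spin populations (> 1 concentrates them).
#' @return A validated `esr` object in eV.
#' @export
#' @examples
#' rec <- generate_synthetic_record(seed = 7, n_atoms = 20)
#' sum(condensed_fukui(rec)$f_plus)
generate_synthetic_record <- function(seed, n_atoms = 10L,
                                      with_energies = TRUE,
                                      with_atoms = TRUE,
                                      delta_max = 0.05,
                                      parr_power = 2) {
  stopifnot(n_atoms >= 1L, delta_max >= 0, parr_power > 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  eps_homo <- stats::runif(1, -9, -5)
  eps_lumo <- eps_homo + stats::runif(1, 2, 7)
  delta <- if (delta_max > 0) stats::runif(3, -delta_max, delta_max) else
    c(0, 0, 0)

  e_n <- e_nm1 <- e_np1 <- eps_somo_anion <- NULL
  if (with_energies) {
    e_n <- stats::runif(1, -30000, -10000)
    e_nm1 <- e_n - eps_homo + delta[1]
    e_np1 <- e_n + eps_lumo - delta[2]
    eps_somo_anion <- eps_lumo + delta[3]
  }

  atoms <- NULL
  if (with_atoms) {
    elements <- sample(c("C", "H", "N", "O", "S"), n_atoms, replace = TRUE,
                       prob = c(0.4, 0.3, 0.15, 0.12, 0.03))
    f_plus <- stats::runif(n_atoms); f_plus <- f_plus / sum(f_plus)
    f_minus <- stats::runif(n_atoms); f_minus <- f_minus / sum(f_minus)
    q_neutral <- stats::runif(n_atoms, -0.5, 0.5)
    q_neutral <- q_neutral - mean(q_neutral)         # sums exactly to charge 0
    sharpen <- function(w) w^parr_power / sum(w^parr_power)
    atoms <- data.frame(
      index = seq_len(n_atoms),
      element = elements,
      q_neutral = q_neutral,
      q_cation = q_neutral + f_minus,                # sums to +1
      q_anion = q_neutral - f_plus,                  # sums to -1
      spin_cation = sharpen(f_minus),
      spin_anion = sharpen(f_plus),
      stringsAsFactors = FALSE
    )
  }

  electronic_structure_record(
    molecule_id = sprintf("synthetic-%d", seed),
    eps_homo = eps_homo, eps_lumo = eps_lumo,
    eps_somo_anion = eps_somo_anion,
    e_n = e_n, e_nm1 = e_nm1, e_np1 = e_np1,
    atoms = atoms,
    unit = "eV",
    method = "synthetic",
    charge_scheme = if (with_atoms) "synthetic-population" else ""
  )
}

#' @export
print.esr <- function(x, ...) {
  cat("<electronic-structure record> ", x$molecule_id, "\n", sep = "")
  cat(sprintf("  HOMO %.4f %s, LUMO %.4f %s", x$eps_homo, x$unit,
              x$eps_lumo, x$unit))
  if (!is.null(x$eps_somo_anion))
    cat(sprintf(", anion SOMO %.4f %s", x$eps_somo_anion, x$unit))
  cat("\n")
  if (!is.null(x$e_n))
    cat(sprintf("  total energies E(N-1), E(N), E(N+1): %.6f, %.6f, %.6f %s\n",
                x$e_nm1, x$e_n, x$e_np1, x$unit))
  if (!is.null(x$atoms))
    cat("  atoms:", nrow(x$atoms),
        if (nzchar(x$charge_scheme)) paste0("(", x$charge_scheme, ")") else "",
        "\n")
  invisible(x)
}

#' Converter stub for quantum-chemistry log files
#'
#' Parsing native quantum-chemistry output is out of scope for this package:
#' records are expected as the documented JSON format, typically produced by
#' a short extraction script next to the calculation. This stub exists so
#' the intended entry point is discoverable; it always signals an error.
#'
#' @param path Path to a quantum-chemistry log file.
#' @export
convert_qc_log <- function(path) {
  stop("conversion from quantum-chemistry log output is not implemented; ",
       "supply records in the documented JSON format (see ?load_record)",
       call. = FALSE)
}
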