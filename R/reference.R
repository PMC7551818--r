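#' Published benchmark values for theopapuamides A-D
#'
#' Reference values for the four theopapuamide marine cyclodepsipeptides at
#' the MN12SX/Def2TZVP level in SMD water, as published: frontier-orbital
#' energies of the neutral species, anion SOMO energy, HOMO-LUMO gap, the
#' four KID compliance descriptors, the global reactivity descriptors, and
#' the hardness-derived pKa. All energies in eV (softness in eV^-1).
#'
#' These values serve as a regression benchmark for the orbital-mode
#' descriptor arithmetic and as the calibration data for
#' [pka_default_model()] and [tce_homo_default]. Two published cells are
#' internally inconsistent with the rest of the benchmark and are documented
#' rather than reproduced: peptide D's softness (0.2012, which is not
#' 1/hardness) and peptide D's nucleophilicity (3.2174, which does not match
#' the TCE reference implied by peptides A-C, whose value would be 2.4452).
#'
#' @return A data frame with one row per peptide and columns `molecule_id`,
#'   `homo`, `lumo`, `somo`, `gap`, `j_i`, `j_a`, `j_hl`, `delta_sl`,
#'   `chi`, `eta`, `omega`, `softness`, `nucleophilicity_n`, `omega_minus`,
#'   `omega_plus`, `net_electrophilicity`, `pka`.
#' @export
#' @examples
#' theopapuamide_reference()[, c("molecule_id", "eta", "pka")]
theopapuamide_reference <- function() {
  data.frame(
    molecule_id = paste("Theopapuamide", c("A", "B", "C", "D")),
    homo = c(-6.3114, -6.2907, -6.3125, -6.6760),
    lumo = c(-0.8210, -1.0710, -0.8893, -0.9040),
    somo = c(-0.8169, -1.0675, -0.8838, -0.8879),
    gap = c(5.4904, 5.2197, 5.4232, 5.7721),
    j_i = c(0.041, 0.042, 0.042, 0.003),
    j_a = c(0.000, 0.002, 0.000, 0.010),
    j_hl = c(0.041, 0.043, 0.042, 0.011),
    delta_sl = c(0.004, 0.004, 0.005, 0.016),
    chi = c(3.5662, 3.6809, 3.6009, 3.7900),
    eta = c(5.4904, 5.2197, 5.4232, 5.7721),
    omega = c(1.1582, 1.2979, 1.1954, 1.2443),
    softness = c(0.1808, 0.1900, 0.1830, 0.2012),
    nucleophilicity_n = c(2.8098, 2.8305, 2.8087, 3.2174),
    omega_minus = c(4.4426, 4.7624, 4.5303, 4.7443),
    omega_plus = c(0.8764, 1.0815, 0.9294, 0.9543),
    net_electrophilicity = c(5.3190, 5.8439, 5.4597, 5.6986),
    pka = c(11.77, 11.99, 11.82, 11.54),
    stringsAsFactors = FALSE
  )
}

#' Load the packaged theopapuamide records
#'
#' Reads the four electronic-structure records shipped with the package
#' (one JSON fixture per peptide, carrying the published frontier-orbital
#' and anion-SOMO energies in eV; total energies were not published and are
#' absent, so on these records KID reports carry `delta_sl` only).
#'
#' @return A named list of four `esr` objects (`A`, `B`, `C`, `D`).
#' @export
#' @examples
#' recs <- theopapuamide_records()
#' compute_global(recs$A)$chi
theopapuamide_records <- function() {
  ids <- c("A", "B", "C", "D")
  recs <- lapply(ids, function(id) {
    path <- system.file("extdata", paste0("theopapuamide_", id, ".json"),
                        package = "cdftkit")
    if (!nzchar(path)) stop("packaged fixture for theopapuamide ", id,
                            " not found", call. = FALSE)
    load_record(path)
  })
  names(recs) <- ids
  recs
}
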