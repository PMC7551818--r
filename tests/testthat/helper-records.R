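# Record with explicit Koopmans deviations: E(N-1)-E(N) = -eps_homo + d_i,
# E(N)-E(N+1) = -eps_lumo + d_a, anion SOMO = LUMO + d_s. compute_kid() on it
# must give j_i = |d_i|, j_a = |d_a|, delta_sl = |d_s|.
koopmans_record <- function(d_i = 0, d_a = 0, d_s = 0,
                            eps_homo = -6.5, eps_lumo = -1.0, e_n = -12345.6,
                            id = "koopmans-test") {
  electronic_structure_record(
    molecule_id = id,
    eps_homo = eps_homo, eps_lumo = eps_lumo,
    eps_somo_anion = eps_lumo + d_s,
    e_n = e_n,
    e_nm1 = e_n - eps_homo + d_i,
    e_np1 = e_n + eps_lumo - d_a,
    unit = "eV"
  )
}

# Minimal per-atom record with caller-supplied populations (sum rules are the
# caller's responsibility; validation can be bypassed for counterexamples).
atom_record <- function(q_neutral, q_cation, q_anion,
                        spin_cation = NULL, spin_anion = NULL,
                        element = NULL, charge = 0L, validate = TRUE) {
  n <- length(q_neutral)
  atoms <- data.frame(index = seq_len(n),
                      element = element %||% rep("C", n),
                      q_neutral = q_neutral, q_cation = q_cation,
                      q_anion = q_anion, stringsAsFactors = FALSE)
  if (!is.null(spin_cation)) atoms$spin_cation <- spin_cation
  if (!is.null(spin_anion)) atoms$spin_anion <- spin_anion
  electronic_structure_record(
    molecule_id = "atoms-test", eps_homo = -6, eps_lumo = -1,
    atoms = atoms, charge = charge, validate = validate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A bare local site table for ranking/comparison tests.
site_table <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$element)) df$element <- rep("C", nrow(df))
  if (is.null(df$index)) df$index <- seq_len(nrow(df))
  class(df) <- c("local_site_table", "data.frame")
  df
}
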