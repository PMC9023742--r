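#' Published binding free-energy component means (bundled reference table)
#'
#' Component means (kcal/mol) of the MM/PBSA binding free energy between the
#' catalytic K-Ras4B(G13D) and SOS(cat) as published for the binary
#' (Ras-SOS) and ternary (Ras-SOS plus allosteric Ras-GTP) systems.  Bundled
#' so the bookkeeping checker ([verify_table2_consistency()]) can audit the
#' internal consistency of the printed rows; the derived rows (`dE_MM`,
#' `dG_solv`, `dG_binding`) are as printed, including a known polar-term
#' sign inconsistency in the binary column.
#'
#' @return Data.frame with columns `component`, `binary`, `ternary`.
#' @export
reference_energy_table <- function() {
  data.frame(
    component = c("dE_vdW", "dE_ele", "dE_polar", "dE_nonpolar",
                  "dE_MM", "dG_solv", "dG_binding"),
    binary = c(-138.73, -154.08, -163.28, -17.00, -292.82, -146.29, -146.53),
    ternary = c(-159.66, -106.65, 128.48, -18.39, -266.31, 110.09, -156.22),
    stringsAsFactors = FALSE)
}

#' Published binding free-energy means with standard deviations
#'
#' As [reference_energy_table()] but including the printed standard
#' deviations; the separately reported binary `dG_binding` mean of -146.54
#' kcal/mol (a rounding variant of the tabulated -146.53) is the value used
#' in the published binary-to-ternary difference of 9.68 kcal/mol.
#'
#' @return A list with `table` (components, means, sds per system) and
#'   `dG_binding_text` (the per-system means as quoted in running text).
#' @export
reference_energy_values <- function() {
  list(table = data.frame(
         component = c("dE_vdW", "dE_ele", "dE_polar", "dE_nonpolar",
                       "dE_MM", "dG_solv", "dG_binding"),
         binary_mean = c(-138.73, -154.08, -163.28, -17.00, -292.82, -146.29, -146.53),
         binary_sd = c(10.29, 22.96, 21.01, 0.87, 25.17, 20.68, 10.28),
         ternary_mean = c(-159.66, -106.65, 128.48, -18.39, -266.31, 110.09, -156.22),
         ternary_sd = c(8.72, 19.62, 17.30, 0.85, 21.90, 16.82, 8.26),
         stringsAsFactors = FALSE),
       dG_binding_text = c(binary = -146.54, ternary = -156.22))
}

#' Audit the bundled published energy table
#'
#' Recomputes the derived rows of the bundled reference table via the
#' bookkeeping identities, checks the published binary-to-ternary binding
#' difference (|-156.22 - (-146.54)| = 9.68 kcal/mol), and flags the binary
#' polar-term sign inconsistency.
#'
#' @param tol Agreement tolerance (kcal/mol), default 0.02.
#' @return A list with `consistency` (the [verify_table2_consistency()]
#'   report), `binding_difference` (recomputed from the quoted means),
#'   `binding_difference_consistent`, and `binary_sign_flag`.
#' @export
verify_paper_tables <- function(tol = 0.02) {
  tab <- reference_energy_table()
  rep <- verify_table2_consistency(tab, tol = tol)
  txt <- reference_energy_values()$dG_binding_text
  diff <- abs(txt[["ternary"]] - txt[["binary"]])
  list(consistency = rep,
       binding_difference = diff,
       binding_difference_consistent = abs(diff - 9.68) < 1e-9,
       binary_sign_flag = any(rep$sign_flag[rep$system == "binary"]))
}
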