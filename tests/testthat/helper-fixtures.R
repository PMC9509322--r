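# Fixture builders shared across tests: everything is generated in code.

fx <- function(name) system.file("extdata", name, package = "bellevans")

# a force_trace from pN values (storage is kJ/mol/nm)
trace_pn <- function(times, forces_pn, ...) {
  force_trace(times, pn_to_kjmolnm(forces_pn), ...)
}

write_xvg_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".xvg",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Minimal PDB writer for pocket-determination tests: one-atom-per-residue
# receptor chains plus a ligand, at chosen coordinates.
write_toy_pdb <- function(receptor, ligand, path = NULL) {
  # receptor/ligand: data frames with resid, resno, elety, elesy, x, y, z
  if (is.null(path))
    path <- withr::local_tempfile(fileext = ".pdb",
                                  .local_envir = parent.frame())
  fmt <- function(rec, i, d) {
    sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, i, d$elety, d$resid, d$resno, d$x, d$y, d$z, d$elesy)
  }
  lines <- character(0)
  n <- 0L
  for (i in seq_len(nrow(receptor))) {
    n <- n + 1L
    lines <- c(lines, fmt("ATOM", n, receptor[i, ]))
  }
  for (i in seq_len(nrow(ligand))) {
    n <- n + 1L
    lines <- c(lines, fmt("HETATM", n, ligand[i, ]))
  }
  writeLines(c(lines, "END"), path)
  path
}

toy_atom <- function(resid, resno, x, y = 0, z = 0, elety = "CA", elesy = "C") {
  data.frame(resid = resid, resno = resno, elety = elety, elesy = elesy,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# Analytic mean of the Bell rupture-force distribution: E[F] = int_0^inf S(f) df
analytic_mean_rupture <- function(params) {
  stats::integrate(function(f) rupture_survival(f, params), 0, Inf,
                   rel.tol = 1e-10)$value
}

table1_fixture <- function() read_table_csv(fx("table1_summary.csv"))
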