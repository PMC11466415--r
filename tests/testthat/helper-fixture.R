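# On-disk fixture builder: one synthetic test case (PDB + Aho map + designs
# + ddG + run config) generated fresh under a temp dir.

make_case_fixture <- function(dir, case_id = "case1", seed = 1,
                              p_match = 0.6, q_sim = 0.5, m = 10,
                              n_cdr3_interface = 10) {
  case_dir <- file.path(dir, case_id)
  toy <- generate_toy_complex(n_cdr3_interface = n_cdr3_interface,
                              seed = seed)
  paths <- write_toy_fixture(toy, case_dir)

  ct <- compute_contacts(toy$structure, c("tcr_alpha", "tcr_beta"),
                         c("peptide", "mhc"))
  pos <- select_design_positions(toy$structure, toy$aho_map,
                                 "cdr3_interface", contacts = ct)
  native <- paste(pos$native_aa, collapse = "")
  ds <- generate_design_set(native, p_match = p_match, q_sim = q_sim,
                            m = m, seed = seed + 1000)
  fasta <- file.path(case_dir, "designs.fasta")
  writeLines(as.vector(rbind(paste0(">", ds$ids), ds$designs)), fasta)

  # ddG table over the designed positions: first half hotspots
  n <- nrow(pos)
  ddg <- data.frame(chain = pos$chain, resnum = pos$resnum,
                    icode = pos$icode,
                    ddg = ifelse(seq_len(n) <= n / 2, 1.2, 0.1))
  ddg_path <- file.path(case_dir, "ddg.tsv")
  write.table(ddg, ddg_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(id = case_id, toy = toy, positions = pos, designs = ds,
       pdb = paths[["pdb"]], aho = paths[["aho"]],
       roles = as.list(toy$structure$role_map),
       designs_path = fasta, ddg = ddg_path)
}

make_run_config <- function(dir, cases, scenario = "cdr3_interface",
                            n_sphere_points = 240) {
  list(
    scenario = scenario,
    cases = lapply(cases, function(cs) {
      list(id = cs$id, pdb = cs$pdb, roles = cs$roles, aho = cs$aho,
           designs = cs$designs_path, ddg = cs$ddg)
    }),
    options = list(n_sphere_points = n_sphere_points),
    output_dir = file.path(dir, "out")
  )
}
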