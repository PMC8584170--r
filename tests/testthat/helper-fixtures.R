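# Small in-code fixtures shared across test files.

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

demo_layout_lines <- function() {
  c("well,role,enzyme,substrate,donor,donor_conc_uM,replicate",
    "A1,standard,,,ATP,500,1",
    "B1,standard,,,ATP,500,2",
    "C1,standard,,,ATP,0,1",
    "D1,standard,,,ATP,0,2",
    "E1,standard,,,ATP,250,1",
    "F1,standard,,,ATP,250,2",
    "C2,reaction,HsdCK,dCyd,ATP,400,1",
    "D2,reaction,HsdCK,dCyd,ATP,400,2",
    "E2,negative_control,,dCyd,ATP,400,1",
    "F2,negative_control,,dCyd,ATP,400,2",
    "G2,substrate_control,HsdCK,dCyd,,,1",
    "H2,substrate_control,HsdCK,dCyd,,,2",
    "A3,basal_control,HsdCK,,ATP,400,1",
    "B3,basal_control,HsdCK,,ATP,400,2",
    "H12,blank,,,,,1")
}

# a matching reader export: readings for every non-blank well
demo_reading_lines <- function() {
  c("well,rlu",
    "A1,57892", "B1,57500", "C1,0", "D1,10", "E1,29000", "F1,28800",
    "C2,20000", "D2,20400",
    "E2,46000", "F2,46200",
    "G2,0", "H2,5",
    "A3,45000", "B3,45100")
}

demo_screen <- function(n_substrates = 3) {
  data.frame(enzyme = "HsdCK",
             substrate = c("dCyd", "Thd", "Urd")[seq_len(n_substrates)],
             donor = "ATP", stringsAsFactors = FALSE)
}

noiseless_config <- function(seed = 1, ...) {
  sim_config(seed = seed, noise_cv = 0, basal_consumption = 0,
             atp_degradation = 0, ...)
}
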