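# crafted AAindex1 record builder shared across test files
make_record <- function(accession, toks, description = "crafted scale") {
  c(paste("H", accession),
    paste("D", description),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste0("     ", paste(toks[1:10], collapse = "   ")),
    paste0("     ", paste(toks[11:20], collapse = "   ")),
    "//")
}
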