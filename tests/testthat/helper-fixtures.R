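# Writes a complete analysis configuration for a generated solenoid: two
# hairpin "domains", their interface, the solenoid helix table, one residue
# pair, and one patch span.
write_solenoid_config <- function(sol, path, chain_override = NULL) {
  ann <- sol$annotation
  ch <- if (is.null(chain_override)) ann$chain[1] else chain_override
  helices <- paste0(
    "      - {chain: ", ch, ", start: ", ann$start, ", end: ", ann$end,
    ", face: ", ann$face, "}"
  )
  writeLines(c(
    "domains:",
    paste0("  - {name: hairpin1, chain: ", ch, ", start: ", ann$start[1],
           ", end: ", ann$end[2], "}"),
    paste0("  - {name: hairpin2, chain: ", ch, ", start: ", ann$start[3],
           ", end: ", ann$end[4], "}"),
    "interfaces:",
    '  - "hairpin1:hairpin2"',
    "solenoids:",
    "  - name: slab",
    "    helices:",
    helices,
    "pairs:",
    paste0("  - {chain_a: ", ch, ", resno_a: ", ann$start[1],
           ", chain_b: ", ch, ", resno_b: ", ann$end[4], "}"),
    "atom: CA",
    "threshold: 7.0",
    "spans:",
    "  - name: ends",
    paste0("    patch_a: {chain: ", ch, ", residues: [", ann$start[1], "]}"),
    paste0("    patch_b: {chain: ", ch, ", residues: [", ann$end[4], "]}")
  ), path)
  path
}
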