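#!/usr/bin/env Rscript
# Per-pair average interaction energies: column totals of the packaged
# hydrogen-bond and hydrophobic tables, dominant components, and the two
# conformational-lock group energies implied by the packaged partition.

suppressPackageStartupMessages(library(conflock))
dir.create("results", showWarnings = FALSE)

t1 <- aggregate_table(sod_energy_table(1))
t2 <- aggregate_table(sod_energy_table(2))
message(sprintf("hydrogen bonds (4 pairs): elec %.2f, vdW %.2f, total %.2f kJ/mol",
                t1$totals["electrostatic"], t1$totals["vdw"], t1$totals["total"]))
message(sprintf("hydrophobic (25 pairs):  elec %.2f, vdW %.2f, total %.2f kJ/mol",
                t2$totals["electrostatic"], t2$totals["vdw"], t2$totals["total"]))

both <- sod_energy_table("both")
dom <- vapply(seq_len(nrow(both)), function(i)
  dominant_component(both[i, ])$component, "")
message(sprintf("vdW-dominated pairs: %d of %d hydrophobic, %d of %d hydrogen-bond",
                sum(dom == "vdw" & both$kind == "hydrophobic"),
                sum(both$kind == "hydrophobic"),
                sum(dom == "vdw" & both$kind == "hydrogen_bond"),
                sum(both$kind == "hydrogen_bond")))

grp <- sod_lock_groups()
g1 <- grp$pair[grp$group == 1]; g2 <- grp$pair[grp$group == 2]
e1 <- lock_energy(g1, both); e2 <- lock_energy(g2, both)
message(sprintf("lock group I  (%d pairs): %.2f kJ/mol", length(g1), e1))
message(sprintf("lock group II (%d pairs): %.2f kJ/mol", length(g2), e2))

utils::write.csv(
  data.frame(quantity = c("hbond_electrostatic", "hbond_vdw", "hbond_total",
                          "hydrophobic_electrostatic", "hydrophobic_vdw",
                          "hydrophobic_total", "lock_group1", "lock_group2"),
             kJ_mol = c(unname(t1$totals), unname(t2$totals), e1, e2)),
  "results/energy_totals.csv", row.names = FALSE)
message("wrote results/energy_totals.csv")
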