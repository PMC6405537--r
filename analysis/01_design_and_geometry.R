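#!/usr/bin/env Rscript
# Step 1: lay out the experiment. Expands the published design (7 trials x
# 6 speakers x 5 calls) into the 210-event broadcast schedule and writes the
# station-by-speaker geometry table (distances, relative altitudes, sectors).

library(kiwidetect)
dir.create("results", showWarnings = FALSE)

design <- rawhiti_design()
schedule <- build_broadcast_schedule(design)
geometry <- rawhiti_geometry()

write.table(schedule, "results/broadcast_schedule.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_geometry_table(geometry, "results/geometry.tsv")

cat("Broadcast schedule:", nrow(schedule), "events over",
    design$n_trials, "trials\n")
cat("Each call segment lasts", design$call_duration_s,
    "s; a full speaker sequence", 5 * design$call_duration_s, "s\n")
cat("Station-speaker distances span",
    paste(range(geometry$distance_m), collapse = " to "), "m;",
    "relative altitudes", paste(range(geometry$relative_altitude_m),
                                collapse = " to "), "m\n")
cat("Wrote results/broadcast_schedule.tsv and results/geometry.tsv\n")
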