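#!/usr/bin/env Rscript
# Stage 1 — simulate the study's raw tables with known ground truth.
#
# Generates one 4-mouse group under the default study conditions: a 379-unit
# sorted population (288 broad-spiking / 91 narrow-spiking, task categories
# matching the recorded cross-tabulation), four daily round-robin
# food-competition sessions for the implanted mid-ranked mouse, 21 days of
# tube-test bouts and warm-spot occupancy, spike trains for every unit, and
# the 21-day intervention bundle. Writes all interchange CSVs to results/.

suppressPackageStartupMessages(library(hierphys))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
cfg <- gen_config(seed = seed, n_units = 379)
out <- "results"
dir.create(out, showWarnings = FALSE)

pop <- generate_unit_population(cfg)
cat(sprintf("population: %d units (%d excitatory / %d inhibitory)\n",
            nrow(pop$units), sum(pop$truth$cell_type == "excitatory"),
            sum(pop$truth$cell_type == "inhibitory")))

trials <- generate_competition_sessions(cfg, "g1")
cat(sprintf("food competition: %d session days, %d trials (%d rows)\n",
            cfg$n_session_days, length(unique(trials$trial_id)), nrow(trials)))

tw <- generate_tube_and_warmspot(cfg, "g1")
spikes <- generate_spike_trains(cfg, trials, pop)
cat(sprintf("spikes: %d events across %d units\n", nrow(spikes),
            length(unique(spikes$unit_id))))

long <- generate_longitudinal(cfg)
waveforms <- generate_waveform_table(pop, cfg)

write_table(trials, file.path(out, "trials.csv"))
write_table(tw$tube, file.path(out, "tube.csv"))
write_table(tw$warmspot, file.path(out, "warmspot.csv"))
write_table(pop$truth, file.path(out, "truth.csv"))
write_table(long$rates, file.path(out, "longitudinal_rates.csv"))
write_table(long$winning, file.path(out, "winning_series.csv"))
# bulky raw event tables go to scratch/ (tens of MB); downstream stages read
# them from there
write_table(spikes, "scratch/raw/spikes.csv")
write_table(waveforms, "scratch/raw/waveforms.csv")
cat("wrote scored tables to results/, raw event tables to scratch/raw/\n")
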