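# shared fixtures: reference medium, channel, bead species, drive
ref_medium <- water_medium()
ref_geometry <- device_geometry()
bead4 <- polystyrene_species(4e-6)
bead1 <- polystyrene_species(1e-6)
bead05 <- polystyrene_species(0.5e-6)

ref_drive <- function(Eac = 7.25) resonant_drive(ref_geometry, ref_medium, Eac = Eac)

# convert a generate_trajectories() data frame into a trajectory list
trajs_from_df <- function(df) {
  lapply(split(df, df$particle_id), function(d) {
    structure(list(id = d$particle_id[1], t = d$t, y = d$y),
              class = "baw_trajectory")
  })
}
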