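# Shared fixtures: reference tables shipped with the package and small
# constructors used across test files.

reference_papp <- function() {
  utils::read.csv(system.file("extdata", "mdck_reference_papp.csv",
                              package = "kpuu"),
                  stringsAsFactors = FALSE)
}

# The fu reference table stores over-unity dialysis ratios as the literal
# token ">100" (percent scale); parse to fraction with a clamp flag.
reference_fu <- function() {
  df <- utils::read.csv(system.file("extdata", "fu_dilution_reference.csv",
                                    package = "kpuu"),
                        stringsAsFactors = FALSE, colClasses = "character")
  parse_pct <- function(x) as.numeric(ifelse(x == ">100", "100", x)) / 100
  for (col in names(df)[-1]) df[[col]] <- parse_pct(df[[col]])
  df
}

# One quantified transport leg with the 96-well geometry.
make_leg <- function(direction, c_receiver, c0 = 1, c_donor = NA_real_,
                     lloq = 0, duration_s = 3600, id = "cpd") {
  geom <- if (direction == "AtoB") transport_geometry(50, 250, 0.0804, duration_s)
    else transport_geometry(250, 50, 0.0804, duration_s)
  transport_measurement(id, direction, c0_donor = c0,
                        c_donor_final = c_donor,
                        c_receiver_final = c_receiver,
                        lloq = lloq, geometry = geom)
}
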