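# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# analysed chord-model cell at +15 deg, default study conditions
cell15 <- function() fixture("cell15", function() {
  g <- make_cell(15, seed = 3)
  list(gen = g, res = analyze_cell(g$frame, cell_id = "c15"))
})

# analysed stripes microculture at +15 deg with nuclei
culture15 <- function() fixture("culture15", function() {
  g <- make_microculture(15, seed = 1)
  list(gen = g, res = analyze_microculture(g$phase, g$nuclei))
})

# axial circular mean (degrees) -- independent of the package's alignment()
axial_mean_deg <- function(a) {
  z <- exp(2i * a * pi / 180)
  Arg(mean(z)) * 90 / pi
}

deg2rad_test <- function(a) a * pi / 180
deg2rad_syn <- deg2rad_test
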