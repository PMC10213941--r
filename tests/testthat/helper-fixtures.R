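# Shared fixtures. The default sweep (8 geometries x 6 loads) is computed
# once per test session and reused by the experiment and acceptance tests.

default_membrane <- membrane_spec()
default_material <- plate_material()

# circular membrane with the printed equal-area radius, for circle oracles
circle_radius_mm <- sqrt(2.031 / pi)
circle_membrane <- membrane_spec(area = pi * circle_radius_mm^2,
                                 perimeter = 2 * pi * circle_radius_mm,
                                 shape = "circle")

get_default_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_sweep(sweep_spec())
    cache
  }
})
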