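# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the reference 100 px layout used by the experiments
ref_layout <- function() cached("ref_layout", ec_layout(100, 10, 0.1))

# a small layout for fast unit tests (50 px -> 28 x 28 grid)
small_layout <- function() cached("small_layout", ec_layout(50, 10, 0.1))

# small, fast clips for pipeline-level tests
small_loom <- function(n_frames = 15) {
  make_square_motion(stim_spec("looming", 40, 220, start_size = 6,
                               end_size = 40, n_frames = n_frames,
                               side_length = 50))
}

small_config <- function(...) loom_config(side_length = 50, ...)

constant_stream <- function(value = 128, side = 50, n = 6, fps = 30) {
  frame_stream(array(value, dim = c(side, side, n)), fps = fps)
}

# memoized full-size model run for the acceptance suite
cached_run <- function(key, stream, config, record = "output") {
  cached(key, run_loom(stream, config, layout = ref_layout(), record = record))
}

ref_suite <- function() cached("ref_suite", loom_suite())
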