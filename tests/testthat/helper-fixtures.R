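# Shared fixtures, built once per test run.

# small random map on an orthorhombic cell, float32-snapped
random_map <- function(dims = c(10, 10, 10), cell_edges = c(10, 10, 10),
                       seed = 1, full_cell = TRUE) {
  set.seed(seed)
  g <- edmapr:::float32(array(rnorm(prod(dims)), dim = dims))
  ngrid <- if (full_cell) dims else dims + 4L
  edmapr:::new_ed_map(g, start = c(0L, 0L, 0L), ngrid = as.integer(ngrid),
                      cell = unit_cell(cell_edges[1], cell_edges[2], cell_edges[3]))
}

# default synthetic entry, cached across tests (rendering is the slow part)
default_entry <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synth_entry(fixture_spec(seed = 7))
    val
  }
})

default_analysis <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      e <- default_entry()
      val <<- analyze_entry(e$structure, e$map, radii = e$spec$radii,
                            keep_cache = TRUE)
    }
    val
  }
})

# tiny 3-residue peptide written through the generator (no jitter)
tiny_structure <- function(seed = 5) {
  synth_structure(fixture_spec(sequences = c(A = "AGS"), coord_jitter = 0,
                               seed = seed))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
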