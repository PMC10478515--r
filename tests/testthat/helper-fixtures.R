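# Shared fixtures: desk-scale geometry and tiny network configurations so
# unit tests run in seconds. All fixtures are generated in code.

tiny_geometry <- function(n = 32L) {
  detector_geometry(n_rows = n, n_cols = n)
}

tiny_beam <- function() beam_profile()

tiny_model_config <- function(input_size = 20L, seed = 1L) {
  model_config(conv1_out_channels = 4L, conv2_out_channels = 4L,
               fc_hidden = 16L, embed_dim = 8L, input_size = input_size,
               seed = seed)
}

# A small labeled dataset of tiny patterns for pipeline tests (images are
# random but deterministic; labels/samples structured for triplet rules).
tiny_patterns <- function(n_per_class = 6L, size = 20L, classes = c("a", "b"),
                          samples_per_class = 2L, seed = 42L) {
  rows <- lapply(seq_along(classes), function(ci) {
    lapply(seq_len(n_per_class), function(i) {
      img <- speckfew:::with_seed(seed + ci * 1000L + i, {
        base <- matrix(stats::runif(size * size), size, size)
        # class-dependent structure: vertical vs horizontal stripes
        stripe <- if (ci == 1L) {
          matrix(sin(seq_len(size) / 2), size, size)
        } else {
          matrix(sin(seq_len(size) / 2), size, size, byrow = TRUE)
        }
        base + 3 * stripe
      })
      tibble::tibble(
        image = list(img), label = classes[ci],
        sample_id = paste0(classes[ci], "_s", (i - 1L) %% samples_per_class + 1L),
        copies = 1L, fluence = 1, seed = seed + i,
        source_id = paste0(classes[ci], "_", i),
        is_augmented = FALSE, partition = NA_character_)
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}

# Fixed-column PDB fixture written at test time.
write_fixture_pdb <- function(path, n_atom = 3L, n_hetatm = 0L) {
  lines <- c("HEADER    TEST FIXTURE")
  fmt <- function(type, i, x, y, z) {
    sprintf("%-6s%5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            type, i, i, x, y, z)
  }
  for (i in seq_len(n_atom)) {
    lines <- c(lines, fmt("ATOM", i, i * 1.5, i * 2.5, i * -1.0))
  }
  for (j in seq_len(n_hetatm)) {
    i <- n_atom + j
    lines <- c(lines, fmt("HETATM", i, i * 1.5, i * 2.5, i * -1.0))
  }
  writeLines(c(lines, "END"), path)
  path
}
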