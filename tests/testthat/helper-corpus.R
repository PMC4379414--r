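# The 20-phantom regression corpus, computed once per test session and
# shared across test files. Phantoms use seeds 1..20 at 96 x 96 x 72; the
# atlas comes from an independent phantom (seed 100) deformed with a smooth
# random warp (seed 101).

.corpus <- new.env(parent = emptyenv())

corpus_shape <- c(96L, 96L, 72L)
corpus_seeds <- 1:20

corpus_atlas <- function() {
  if (is.null(.corpus$atlas)) {
    ph <- generate_phantom(phantom_spec(shape = corpus_shape, seed = 100L))
    .corpus$atlas <- derive_atlas(ph, warp_amplitude = 2, seed = 101L)
  }
  .corpus$atlas
}

run_one_phantom <- function(seed, atlas) {
  ph <- generate_phantom(phantom_spec(shape = corpus_shape, seed = seed))
  seg <- tryCatch(suppressWarnings(wrist_segment(ph$volume, atlas)),
                  error = function(e) e)
  if (inherits(seg, "error"))
    return(list(seed = seed, ok = FALSE, error = conditionMessage(seg)))
  rep <- evaluate_labels(ph$labels, seg$labels, labels = 1:15)
  # marker purity: fraction of each stage's object-marker voxels lying
  # inside the matching ground-truth bone
  wl <- wrist_labels()
  purity <- c()
  for (st in c("radioulnar", "metacarpal", "carpal")) {
    ms <- seg$stages[[st]]$markers
    for (nm in names(ms$objects)) {
      l <- wl$label[wl$code == nm]
      if (length(l) != 1) next
      mk <- ms$objects[[nm]]
      purity[paste0(st, ".", nm)] <- mean(ph$labels[mk] == l)
    }
  }
  list(seed = seed, ok = TRUE, labels = seg$labels, report = rep,
       ru_slice = seg$stages$radioulnar$slice,
       mc_slice = seg$stages$metacarpal$slice,
       purity = purity, truth_labels = ph$labels)
}

corpus_results <- function() {
  if (is.null(.corpus$results)) {
    atlas <- corpus_atlas()
    .corpus$results <- lapply(corpus_seeds, run_one_phantom, atlas = atlas)
  }
  .corpus$results
}

# an independent second pass over the corpus, kept only as label maps
corpus_second_pass_labels <- function() {
  if (is.null(.corpus$second)) {
    atlas <- corpus_atlas()
    .corpus$second <- lapply(corpus_seeds, function(s) {
      ph <- generate_phantom(phantom_spec(shape = corpus_shape, seed = s))
      seg <- tryCatch(suppressWarnings(wrist_segment(ph$volume, atlas)),
                      error = function(e) NULL)
      if (is.null(seg)) NULL else seg$labels
    })
  }
  .corpus$second
}
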