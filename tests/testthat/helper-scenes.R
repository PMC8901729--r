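# Small shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# static 64 px phantom scene + params, no motion
staticScene <- function() fixture("static_scene", function() {
  sc <- makeScene(sceneConfig("phantom", n_pix = 64L, seed = 3,
                              motion = list(kind = "none")))
  list(scene = sc, params = sceneParams(sc))
})

# a noiseless static acquisition of 60 spokes
staticNoiselessK <- function() fixture("static_noiseless_k", function() {
  s <- staticScene()
  simulateAcquisition(s$scene, s$params, 60L, seed = 1L, noise_sigma = 0)
})

# learning data + single-bin library + basis on the static scene (noiseless)
staticLibrary <- function() fixture("static_library", function() {
  s <- staticScene()
  k <- simulateAcquisition(s$scene, s$params, 400L, seed = 5L, noise_sigma = 0)
  pw <- prewhitenAndCompress(k, estimateNoise(k), 1.0)
  lib <- buildLibrary(pw$k, rep(1L, 400L))
  list(k = pw$k, model = pw$model, lib = lib,
       basis = polynomialBasis(64L), scene = s$scene, params = s$params)
})

relErr <- function(a, b) max(abs(a - b)) / max(abs(b))
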