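# Shared fixtures, built once per test run and cached. Everything is
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_phantom <- function() fixture("phantom", make_phantom)

fx_fodf_left <- function() fixture("fodf_left", function()
  default_phantom_fodf(fx_phantom(), hemispheres = "left"))

fx_tracking_phantom <- function() fixture("tracking_phantom", make_tracking_phantom)

# 50 tracked streamlines on the clean straight-bundle phantom
fx_tracked_bundle <- function() fixture("tracked_bundle", function() {
  ph <- fx_tracking_phantom()
  track(bundle_protocol(50L), ph$field, ph$rois, seed = 11L)
})

# the standard FBC phantom: 50 coherent + 10 injected spurious streamlines
fx_fbc_set <- function() fixture("fbc_set", function() {
  cl <- cbind(seq(0, 40, length.out = 60), 0, 0)
  b <- make_bundle(cl, 50L, tube_radius_mm = 2, seed = 1L)
  fbc_scores(inject_spurious(b, 0.2, seed = 2L))
})

# small unit-affine binary mask from a logical/numeric 3D array
mask3 <- function(arr, affine = diag(4)) {
  scalar_map(array(as.numeric(arr != 0), dim(arr)), affine, "binary")
}

random_mask <- function(dm, p = 0.3) {
  mask3(array(stats::runif(prod(dm)) < p, dm))
}
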