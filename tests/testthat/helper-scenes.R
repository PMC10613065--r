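# Small scene factories: full default appearance, reduced grain counts,
# so unit tests stay fast.

tiny_params <- function(n_filled = 8, n_unfilled = 4, seed = 1, ...) {
  args <- list(n_filled = n_filled, n_unfilled = n_unfilled,
               n_specks = 5, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_params, args)
}
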