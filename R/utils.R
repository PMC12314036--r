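# Seed hygiene: seeded operations must be reproducible without trampling the
# caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Clamp values implied by a drug profile: inhibit -> -1, activate -> +1.
profile_clamps <- function(profile) {
  stopifnot(inherits(profile, "drug_profile"))
  v <- ifelse(profile$targets$action == "inhibit", -1, 1)
  stats::setNames(v, profile$targets$protein)
}
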