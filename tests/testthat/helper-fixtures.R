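# Shared fixtures: small phantoms, short schedules, oracle networks.

toyPhantom <- function(seed = 1, side = 64) {
  g <- max(side, 64)
  img <- generatePhantom2D(PhantomSpec(height = g, width = g, seed = seed))
  img[seq_len(side), seq_len(side)]
}

# short schedule whose terminal state is noise-dominated
toySchedule <- function(Tsteps = 50) buildSchedule(Tsteps, 0.004, 0.35)

# oracle epsilon-predictor that steers sampling exactly to the teacher x0
teacherOracle <- function(x0, schedule) {
  force(x0); force(schedule)
  function(xt, t, cond, j) {
    ab <- schedule@alphaBar[t]
    list(epsHat = (xt - sqrt(ab) * x0) / sqrt(1 - ab))
  }
}

# oracle that reconstructs the condition itself (identity restoration)
identityOracle <- function(schedule) {
  force(schedule)
  function(xt, t, cond, j) {
    x0 <- if (length(dim(cond)) == 3) cond[, , 1] else cond
    ab <- schedule@alphaBar[t]
    list(epsHat = (xt - sqrt(ab) * x0) / sqrt(1 - ab))
  }
}

# oracle producing the linear blend of the two condition layers at index j
linearBlendOracle <- function(schedule, R) {
  force(schedule); force(R)
  function(xt, t, cond, j) {
    b <- ((R + 1 - j) * cond[, , 1] + j * cond[, , 2]) / (R + 1)
    ab <- schedule@alphaBar[t]
    list(epsHat = (xt - sqrt(ab) * b) / sqrt(1 - ab))
  }
}

# oracle that returns a fixed target per successive sampling call
sequenceOracle <- function(schedule, targets) {
  env <- new.env()
  env$call <- 0L
  lastT <- schedule@Tsteps
  function(xt, t, cond, j) {
    if (t == lastT) env$call <- env$call + 1L
    x0 <- targets[[min(env$call, length(targets))]]
    ab <- schedule@alphaBar[t]
    list(epsHat = (xt - sqrt(ab) * x0) / sqrt(1 - ab))
  }
}

# phase-correlation translation estimate between two images (test oracle)
phaseCorrPeak <- function(a, b) {
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cp <- Fa * Conj(Fb)
  r <- Re(stats::fft(cp / pmax(Mod(cp), 1e-12), inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  shift <- pk - 1L
  if (shift[1] > nrow(a) / 2) shift[1] <- shift[1] - nrow(a)
  if (shift[2] > ncol(a) / 2) shift[2] <- shift[2] - ncol(a)
  -shift  # (dy, dx) with a(r, c) ~ b(r + dy, c + dx)
}

tinyVolume <- function(seed = 1, side = 48, depth = 31) {
  generatePhantomVolume(PhantomSpec(height = side, width = side,
                                    depth = depth, seed = seed,
                                    nOrganelles = 4))
}
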