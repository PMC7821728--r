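# Shared fixtures, built in code.

toyElectrodeTable <- function(n = 4, group = "LA", excluded = integer()) {
  data.frame(
    Electrode = seq_len(n),
    Label = paste0(group, seq_len(n)),
    x = 0, y = 0, z = 0,
    AnatomicalLabel = rep_len(c("superior temporal gyrus",
                                "middle temporal gyrus"), n),
    Group = group,
    Excluded = seq_len(n) %in% excluded,
    stringsAsFactors = FALSE
  )
}

# trial tensor with prescribed power values (trial x freq x time)
toyTensor <- function(power, timeAxis, frequencies,
                      conditions = rep("A", dim(power)[1]),
                      outliers = rep(FALSE, dim(power)[1]),
                      unit = "power") {
  new("TrialTensor",
      electrode = 1L,
      power = power,
      phase = array(0, dim(power)),
      timeAxis = timeAxis,
      frequencies = frequencies,
      trialMeta = data.frame(
        trial_number = seq_len(dim(power)[1]),
        block = "001",
        condition = conditions,
        is_outlier = outliers,
        stringsAsFactors = FALSE),
      lockingEvent = "Trial",
      unit = unit)
}

# tensor with constant power `pre` before t=0 and `post` after, for
# baseline-unit closed forms
stepTensor <- function(pre = 1, post = 2, nTrials = 3, nFreq = 2,
                       rate = 100, tmin = -1, tmax = 1) {
  timeAxis <- seq(tmin, tmax - 1 / rate, by = 1 / rate)
  p <- ifelse(timeAxis < 0, pre, post)
  power <- aperm(array(p, c(length(timeAxis), nTrials, nFreq)), c(2, 3, 1))
  toyTensor(power, timeAxis, seq_len(nFreq) * 10)
}

# small simulated dataset shared across test files (computed once)
sharedSimEnv <- new.env()
sharedSim <- function() {
  if (is.null(sharedSimEnv$sim)) {
    sharedSimEnv$sim <- simulateDataset(simulationSpec(
      nSubjects = 1, electrodesPerSubject = 4, trialsPerBlock = 20,
      sampleRate = 500, seed = 101))
  }
  sharedSimEnv$sim
}

# brute-force Benjamini-Hochberg, the independent reference for p.adjust
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)                 # rank of p[i]
    adj[i] <- min(1, min(p[o][r:m] * m / (r:m)))
  }
  adj
}
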