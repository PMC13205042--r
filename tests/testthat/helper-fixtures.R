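## Shared fixtures: templates are deterministic, so build once per session.
clickTpl <- makeTemplate("click")
daTpl <- makeTemplate("da40")

## Bare averaged response around an arbitrary waveform (click/da epoch).
mkAvg <- function(a, rate = 20000, t0 = -5, stim = "da40", pid = "fix") {
  new("AveragedResponse", amplitude = a, samplingRate = rate, t0Offset = t0,
      stimulusKind = stim, participantId = pid,
      composition = data.frame(channel = "A", polarity = "condensation",
                               n = 1L, stringsAsFactors = FALSE),
      provenance = "fixture")
}

## Sweep buffer holding an explicit matrix.
mkBuf <- function(d, channel = "A", polarity = "condensation",
                  stim = "click", rate = 20000, t0 = -5, pid = "fix",
                  coll = 1L) {
  new("SweepBuffer", data = d, samplingRate = rate, t0Offset = t0,
      channel = channel, polarity = polarity, stimulusKind = stim,
      participantId = pid, collectionIndex = coll, filterApplied = "")
}

## The four balanced da40 buffers for one simulated participant.
simDaBuffers <- function(nm, n, seedBase, tpl = daTpl, pid = "fix") {
  list(Acond = simulateSweeps(tpl, nm, n, "A", "condensation", pid,
                              seed = seedBase + 1),
       Arare = simulateSweeps(tpl, nm, n, "A", "rarefaction", pid,
                              seed = seedBase + 2),
       Bcond = simulateSweeps(tpl, nm, n, "B", "condensation", pid,
                              seed = seedBase + 3),
       Brare = simulateSweeps(tpl, nm, n, "B", "rarefaction", pid,
                              seed = seedBase + 4))
}
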