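synthetic_rp4_like_trace.csv
  A fully synthetic stand-in for an intracellular membrane-potential
  recording (mV scale, 2 ms sampling): an NLARI background fluctuation with
  sparse added spikes. Generated once with a fixed seed; used by examples
  and tests that exercise the recording-driven code paths. It is NOT a real
  recording and carries no electrophysiological meaning.
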