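#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step population simulation of the four-state promoter model.
// States: 1 = ON, 2 = OFF1, 3 = OFF2a, 4 = OFF2b.
// Per step: initiation while ON as Poisson(kIni*dt); promoter transition
// with probability rate*dt; each nascent RNA converts to mature with
// probability kRelease*dt; each mature RNA decays with probability kDeg*dt.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_population(NumericVector rates,
                                      IntegerVector initState,
                                      int nSteps, double dt) {
  const double kOn1 = rates["kOn1"], kOff1 = rates["kOff1"],
               kOff2 = rates["kOff2"], f1 = rates["f1"],
               kOn2a = rates["kOn2a"], kOn2b = rates["kOn2b"],
               kIni = rates["kIni"], kRelease = rates["kRelease"],
               kDeg = rates["kDeg"];
  const int nCells = initState.size();
  const double pOff1 = kOff1 * dt;
  const double pOn1 = kOn1 * dt;
  const double pTo2a = f1 * kOff2 * dt;
  const double pTo2b = (1.0 - f1) * kOff2 * dt;
  const double pOn2a = kOn2a * dt;
  const double pOn2b = kOn2b * dt;
  const double pRel = kRelease * dt;
  const double pDeg = kDeg * dt;
  const double muIni = kIni * dt;

  IntegerMatrix out(nCells, 3);
  for (int c = 0; c < nCells; ++c) {
    int state = initState[c];
    int nasc = 0, mat = 0;
    for (int s = 0; s < nSteps; ++s) {
      if (state == 1 && muIni > 0.0)
        nasc += (int) R::rpois(muIni);
      // promoter transition based on the state at the step start
      double u = unif_rand();
      switch (state) {
      case 1:
        if (u < pOff1) state = 2;
        break;
      case 2:
        if (u < pOn1) state = 1;
        else if (u < pOn1 + pTo2a) state = 3;
        else if (u < pOn1 + pTo2a + pTo2b) state = 4;
        break;
      case 3:
        if (u < pOn2a) state = 2;
        break;
      default:
        if (u < pOn2b) state = 2;
      }
      if (nasc > 0 && pRel > 0.0) {
        int rel = (int) R::rbinom((double) nasc, pRel);
        nasc -= rel;
        mat += rel;
      }
      if (mat > 0 && pDeg > 0.0)
        mat -= (int) R::rbinom((double) mat, pDeg);
    }
    out(c, 0) = nasc;
    out(c, 1) = mat;
    out(c, 2) = state;
  }
  return out;
}
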