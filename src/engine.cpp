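// Time-stepped co-simulation of the column: forward-Euler aEIF neurons,
// conductance synapses maintained as two auxiliary exponential decays per
// receptor (mathematically identical to the direct double-exponential sum),
// Tsodyks-Markram short-term plasticity evaluated at spike emission, and a
// ring buffer for delayed spike delivery. Fully deterministic: all
// randomness (connectivity, stimulus) is drawn in R beforehand.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Receptor {
  double gmax, Erev, tauOn, tauOff;
  int delaySteps;
  double decOn, decOff;
};

static Receptor makeReceptor(const List& blk, double dt) {
  Receptor r;
  r.gmax = as<double>(blk["g_max"]);
  r.Erev = as<double>(blk["E_rev"]);
  r.tauOn = as<double>(blk["tau_on"]);
  r.tauOff = as<double>(blk["tau_off"]);
  double tauD = as<double>(blk["tau_D"]);
  int steps = (int)std::lround(tauD / dt);
  if (steps < 1) steps = 1; // delays shorter than dt round up to one step
  r.delaySteps = steps;
  r.decOn = std::exp(-dt / r.tauOn);
  r.decOff = std::exp(-dt / r.tauOff);
  return r;
}

// [[Rcpp::export(name = ".run_column_cpp")]]
List run_column_cpp(NumericVector C, NumericVector gL, NumericVector EL,
                    NumericVector Vr, NumericVector Vth, NumericVector DeltaT,
                    NumericVector tauw, NumericVector a_sub, NumericVector b_sp,
                    NumericVector Ibg, LogicalVector excitatory,
                    IntegerVector pre, IntegerVector post,
                    List ampa, List nmda, List gaba, List stp,
                    IntegerVector stimNeuron, IntegerVector stimOn,
                    IntegerVector stimOff, NumericVector stimAmp,
                    double dt, int nSteps, bool canonicalExp, double expClamp,
                    IntegerVector traceIds, int traceEvery) {
  const int n = C.size();
  const int nSyn = pre.size();

  Receptor rA = makeReceptor(ampa, dt);
  Receptor rN = makeReceptor(nmda, dt);
  Receptor rG = makeReceptor(gaba, dt);
  const double U = as<double>(stp["U"]);
  const double tauF = as<double>(stp["tau_facil"]);
  const double tauR = as<double>(stp["tau_rec"]);

  // CSR adjacency: outgoing targets per presynaptic neuron
  std::vector<int> outOff(n + 1, 0), outTgt(nSyn);
  for (int s = 0; s < nSyn; ++s) outOff[pre[s]]++; // shifted histogram
  for (int i = 0; i < n; ++i) outOff[i + 1] += outOff[i]; // block offsets
  {
    std::vector<int> cur(outOff.begin(), outOff.end() - 1);
    for (int s = 0; s < nSyn; ++s) {
      outTgt[cur[pre[s] - 1]++] = post[s] - 1;
    }
  }

  // neuron state
  std::vector<double> V(EL.begin(), EL.end());
  std::vector<double> w(n, 0.0);
  // conductance aux decays: on/off accumulator per receptor per neuron
  std::vector<double> sOnA(n, 0), sOffA(n, 0), sOnN(n, 0), sOffN(n, 0),
      sOnG(n, 0), sOffG(n, 0);
  // per-presynaptic-neuron STP state (shared by all outgoing connections,
  // which see the same spike train and the same constants)
  std::vector<double> stpU(n, 0), stpR(n, 0), stpT(n, 0);
  std::vector<char> stpInit(n, 0);

  // delayed delivery ring buffers: (neuron emitting, efficiency a)
  int maxDelay = std::max(std::max(rA.delaySteps, rN.delaySteps),
                          rG.delaySteps);
  int ring = maxDelay + 1;
  std::vector<std::vector<std::pair<int, double> > > queue(ring);

  // stimulus step deltas
  std::vector<double> stimCur(n, 0.0);
  const int nSeg = stimNeuron.size();
  // sort segment boundaries by step via bucket lists
  std::vector<std::vector<std::pair<int, double> > > addAt(nSteps + 2),
      subAt(nSteps + 2);
  for (int s = 0; s < nSeg; ++s) {
    int on = stimOn[s], off = stimOff[s];
    if (on >= 1 && on <= nSteps)
      addAt[on].push_back(std::make_pair(stimNeuron[s] - 1, stimAmp[s]));
    if (off >= 1 && off <= nSteps)
      subAt[off].push_back(std::make_pair(stimNeuron[s] - 1, stimAmp[s]));
  }

  std::vector<int> spkNeuron;
  std::vector<double> spkTime;
  spkNeuron.reserve(1 << 16);
  spkTime.reserve(1 << 16);
  double delivered = 0.0;

  const int nTrace = traceIds.size();
  int nTraceRows = nTrace > 0 ? nSteps / traceEvery + 1 : 0;
  NumericMatrix traces(nTraceRows, nTrace);
  if (nTrace > 0)
    for (int j = 0; j < nTrace; ++j) traces(0, j) = V[traceIds[j] - 1];

  const double nmdaScale = 1.08, nmdaCoef = 0.19, nmdaSlope = 0.064;

  for (int k = 0; k < nSteps; ++k) {
    // (1) deliver due events enqueued delaySteps ago
    std::vector<std::pair<int, double> >& due = queue[k % ring];
    for (size_t e = 0; e < due.size(); ++e) {
      int src = due[e].first;
      double aEff = due[e].second;
      bool exc = excitatory[src];
      for (int q = outOff[src]; q < outOff[src + 1]; ++q) {
        int tgt = outTgt[q];
        if (exc) {
          sOnA[tgt] += aEff; sOffA[tgt] += aEff;
          sOnN[tgt] += aEff; sOffN[tgt] += aEff;
        } else {
          sOnG[tgt] += aEff; sOffG[tgt] += aEff;
        }
        delivered += 1.0;
      }
    }
    due.clear();

    // stimulus bookkeeping for this step
    {
      std::vector<std::pair<int, double> >& ad = addAt[k + 1];
      for (size_t e = 0; e < ad.size(); ++e) stimCur[ad[e].first] += ad[e].second;
      std::vector<std::pair<int, double> >& sb = subAt[k + 1];
      for (size_t e = 0; e < sb.size(); ++e) stimCur[sb[e].first] -= sb[e].second;
    }

    double tNext = (k + 1) * dt;
    // (2) currents at current V, (3) Euler step, (4) threshold/reset
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      double sv = nmdaScale / (1.0 + nmdaCoef * std::exp(-nmdaSlope * v));
      double Isyn = rA.gmax * (sOffA[i] - sOnA[i]) * (v - rA.Erev) +
                    rN.gmax * sv * (sOffN[i] - sOnN[i]) * (v - rN.Erev) +
                    rG.gmax * (sOffG[i] - sOnG[i]) * (v - rG.Erev);
      double arg = (v - Vth[i]) / DeltaT[i];
      if (arg > expClamp) arg = expClamp;
      double pref = canonicalExp ? gL[i] * DeltaT[i] : gL[i];
      double dV = (-gL[i] * (v - EL[i]) + pref * std::exp(arg) + Ibg[i] +
                   stimCur[i] - Isyn - w[i]) / C[i];
      double dw = (a_sub[i] * (v - EL[i]) - w[i]) / tauw[i];
      double vNew = v + dt * dV;
      double wNew = w[i] + dt * dw;
      if (!std::isfinite(vNew) || !std::isfinite(wNew)) {
        stop("state became non-finite for neuron %d at t = %.3f ms", i + 1,
             tNext);
      }
      if (vNew > Vth[i]) {
        vNew = Vr[i];
        wNew += b_sp[i];
        spkNeuron.push_back(i + 1);
        spkTime.push_back(tNext);
        // (5) STP at emission time, enqueue one delivery per receptor delay
        double uS, rS;
        if (!stpInit[i]) {
          uS = U; rS = 1.0 - U; stpInit[i] = 1;
        } else {
          double dtSp = tNext - stpT[i];
          double ef = std::exp(-dtSp / tauF), er = std::exp(-dtSp / tauR);
          uS = stpU[i] * ef + U * (1.0 - stpU[i] * ef);
          rS = stpR[i] * (1.0 - uS) * er + 1.0 - er;
        }
        stpU[i] = uS; stpR[i] = rS; stpT[i] = tNext;
        double aEff = uS * rS;
        int dl = excitatory[i] ? rA.delaySteps : rG.delaySteps;
        queue[(k + 1 + dl) % ring].push_back(std::make_pair(i, aEff));
      }
      V[i] = vNew;
      w[i] = wNew;
    }

    // (6) decay conductance accumulators to the next step
    for (int i = 0; i < n; ++i) {
      sOnA[i] *= rA.decOn; sOffA[i] *= rA.decOff;
      sOnN[i] *= rN.decOn; sOffN[i] *= rN.decOff;
      sOnG[i] *= rG.decOn; sOffG[i] *= rG.decOff;
    }

    if (nTrace > 0 && (k + 1) % traceEvery == 0) {
      int row = (k + 1) / traceEvery;
      for (int j = 0; j < nTrace; ++j) traces(row, j) = V[traceIds[j] - 1];
    }
  }

  return List::create(_["neuron_id"] = wrap(spkNeuron),
                      _["time"] = wrap(spkTime),
                      _["traces"] = traces,
                      _["delivered"] = delivered);
}
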