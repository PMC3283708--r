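#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie direct method) simulation of the joint
// (FKBP occupancy x C/O gating) continuous-time Markov chain.
//
// Occupancy coding: 0 = Free, 1 = 12, 2 = 12*, 3 = 12.6, 4 = 12.6*.
// Gate coding:      0 = closed, 1 = open.
//
// rates: k1, k_m1, k2, k_m2, k3, k_m3, k4, k_m4, kC   (length 9)
// kO_occ: opening rate while in each occupancy state   (length 5)
// seg_start / seg_f12 / seg_f126: piecewise-constant ligand schedule (uM);
//   seg_start[0] must be 0. Concentration switches are applied by truncating
//   the current waiting time at the boundary and re-drawing (exact, by
//   memorylessness of the exponential distribution).
// window: width (s) for open-time accumulation; must be > 0.
//
// Uses R's RNG (caller controls the seed via set.seed()).
// [[Rcpp::export]]
List gillespie_core(NumericVector rates, NumericVector kO_occ,
                    NumericVector seg_start, NumericVector seg_f12,
                    NumericVector seg_f126, double duration, double window,
                    int init_occ, int init_gate, bool record_path) {
  const double k1 = rates[0], k_m1 = rates[1], k2 = rates[2], k_m2 = rates[3],
               k3 = rates[4], k_m3 = rates[5], k4 = rates[6], k_m4 = rates[7],
               kC = rates[8];

  const int nseg = seg_start.size();
  const int nwin = (int)std::ceil(duration / window - 1e-9);
  NumericVector open_time(nwin);

  std::vector<double> ev_t;
  std::vector<int> ev_occ, ev_gate;
  if (record_path) {
    ev_t.push_back(0.0);
    ev_occ.push_back(init_occ);
    ev_gate.push_back(init_gate);
  }

  RNGScope scope;
  double t = 0.0;
  int occ = init_occ, gate = init_gate;
  int seg = 0;

  // up to 3 occupancy transitions leave any state, plus one gating transition
  double rate[4];
  int to_occ[4], to_gate[4];

  while (t < duration) {
    while (seg + 1 < nseg && seg_start[seg + 1] <= t) ++seg;
    const double f12 = seg_f12[seg], f126 = seg_f126[seg];
    const double seg_end =
        (seg + 1 < nseg && seg_start[seg + 1] < duration) ? seg_start[seg + 1]
                                                          : duration;

    int n = 0;
    switch (occ) {
    case 0:
      rate[n] = k1 * f12;  to_occ[n] = 1; to_gate[n] = gate; ++n;
      rate[n] = k3 * f126; to_occ[n] = 3; to_gate[n] = gate; ++n;
      break;
    case 1:
      rate[n] = k_m1; to_occ[n] = 0; to_gate[n] = gate; ++n;
      rate[n] = k2;   to_occ[n] = 2; to_gate[n] = gate; ++n;
      break;
    case 2:
      rate[n] = k_m2; to_occ[n] = 1; to_gate[n] = gate; ++n;
      break;
    case 3:
      rate[n] = k_m3; to_occ[n] = 0; to_gate[n] = gate; ++n;
      rate[n] = k4;   to_occ[n] = 4; to_gate[n] = gate; ++n;
      break;
    case 4:
      rate[n] = k_m4; to_occ[n] = 3; to_gate[n] = gate; ++n;
      break;
    }
    rate[n] = (gate == 0) ? kO_occ[occ] : kC;
    to_occ[n] = occ; to_gate[n] = 1 - gate; ++n;

    double total = 0.0;
    for (int i = 0; i < n; ++i) total += rate[i];

    double t_next;
    bool is_event;
    if (total <= 0.0) {
      t_next = seg_end;
      is_event = false;
    } else {
      const double dt = R::exp_rand() / total;
      if (t + dt >= seg_end) {
        t_next = seg_end;
        is_event = false;
      } else {
        t_next = t + dt;
        is_event = true;
      }
    }

    if (gate == 1 && t_next > t) {
      // accumulate open time into the overlapped windows
      int w0 = (int)std::floor(t / window);
      int w1 = (int)std::floor(t_next / window);
      if (w1 >= nwin) w1 = nwin - 1;
      for (int w = w0; w <= w1; ++w) {
        const double lo = std::max(t, w * window);
        const double hi = std::min(t_next, (w + 1) * window);
        if (hi > lo) open_time[w] += hi - lo;
      }
    }

    t = t_next;
    if (is_event) {
      double u = unif_rand() * total;
      int pick = 0;
      double acc = rate[0];
      while (u > acc && pick < n - 1) acc += rate[++pick];
      occ = to_occ[pick];
      gate = to_gate[pick];
      if (record_path) {
        ev_t.push_back(t);
        ev_occ.push_back(occ);
        ev_gate.push_back(gate);
      }
    }
  }

  return List::create(_["open_time"] = open_time,
                      _["times"] = record_path ? wrap(ev_t) : R_NilValue,
                      _["occupancy"] = record_path ? wrap(ev_occ) : R_NilValue,
                      _["gate"] = record_path ? wrap(ev_gate) : R_NilValue,
                      _["final_occ"] = occ, _["final_gate"] = gate);
}
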