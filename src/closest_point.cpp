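#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to point p, after Ericson,
// "Real-Time Collision Detection", ch. 5.1.5.  Returns the closest
// point in cp[3] and barycentric coordinates in bary[3].
static void closestPointTriangle(const double *p, const double *a,
                                 const double *b, const double *c,
                                 double *cp, double *bary) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i];
        ac[i] = c[i] - a[i];
        ap[i] = p[i] - a[i];
    }
    double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
    double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
    if (d1 <= 0.0 && d2 <= 0.0) {
        for (int i = 0; i < 3; ++i) cp[i] = a[i];
        bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
        return;
    }
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
        for (int i = 0; i < 3; ++i) cp[i] = b[i];
        bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
        return;
    }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) cp[i] = a[i] + v*ab[i];
        bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
        return;
    }
    double cpv[3];
    for (int i = 0; i < 3; ++i) cpv[i] = p[i] - c[i];
    double d5 = ab[0]*cpv[0] + ab[1]*cpv[1] + ab[2]*cpv[2];
    double d6 = ac[0]*cpv[0] + ac[1]*cpv[1] + ac[2]*cpv[2];
    if (d6 >= 0.0 && d5 <= d6) {
        for (int i = 0; i < 3; ++i) cp[i] = c[i];
        bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
        return;
    }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double w = d2 / (d2 - d6);
        for (int i = 0; i < 3; ++i) cp[i] = a[i] + w*ac[i];
        bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
        return;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int i = 0; i < 3; ++i) cp[i] = b[i] + w*(c[i] - b[i]);
        bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
        return;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    for (int i = 0; i < 3; ++i) cp[i] = a[i] + ab[i]*v + ac[i]*w;
    bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

// For each query point, the exact closest point over all mesh triangles.
// A centroid-radius lower bound prunes most triangles; the result is
// identical to the exhaustive scan.
// [[Rcpp::export(name = ".cppClosestOnMesh")]]
List cppClosestOnMesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
    const int n = P.nrow(), nt = F.nrow();
    if (nt == 0) stop("mesh has no triangles");
    std::vector<double> cx(nt), cy(nt), cz(nt), rad(nt);
    for (int t = 0; t < nt; ++t) {
        int ia = F(t,0)-1, ib = F(t,1)-1, ic = F(t,2)-1;
        double ax=V(ia,0), ay=V(ia,1), az=V(ia,2);
        double bx=V(ib,0), by=V(ib,1), bz=V(ib,2);
        double qx=V(ic,0), qy=V(ic,1), qz=V(ic,2);
        cx[t]=(ax+bx+qx)/3.0; cy[t]=(ay+by+qy)/3.0; cz[t]=(az+bz+qz)/3.0;
        double r2 = 0.0, d2;
        d2=(ax-cx[t])*(ax-cx[t])+(ay-cy[t])*(ay-cy[t])+(az-cz[t])*(az-cz[t]);
        if (d2>r2) r2=d2;
        d2=(bx-cx[t])*(bx-cx[t])+(by-cy[t])*(by-cy[t])+(bz-cz[t])*(bz-cz[t]);
        if (d2>r2) r2=d2;
        d2=(qx-cx[t])*(qx-cx[t])+(qy-cy[t])*(qy-cy[t])+(qz-cz[t])*(qz-cz[t]);
        if (d2>r2) r2=d2;
        rad[t] = std::sqrt(r2);
    }
    NumericMatrix CP(n,3), BARY(n,3);
    NumericVector D(n);
    IntegerVector TRI(n);
    double p[3], a[3], b[3], c[3], cp[3], bary[3];
    double bcp[3], bbary[3];
    for (int q = 0; q < n; ++q) {
        p[0]=P(q,0); p[1]=P(q,1); p[2]=P(q,2);
        // seed upper bound from the nearest centroid
        int seed = 0; double best = R_PosInf;
        for (int t = 0; t < nt; ++t) {
            double dx=p[0]-cx[t], dy=p[1]-cy[t], dz=p[2]-cz[t];
            double dc = std::sqrt(dx*dx+dy*dy+dz*dz);
            if (dc < best) { best = dc; seed = t; }
        }
        double bestD = R_PosInf; int bestT = seed;
        for (int pass = 0; pass < 2; ++pass) {
            for (int t = 0; t < nt; ++t) {
                if (pass == 0 && t != seed) continue;
                if (pass == 1 && t == seed) continue;
                double dx=p[0]-cx[t], dy=p[1]-cy[t], dz=p[2]-cz[t];
                double dc = std::sqrt(dx*dx+dy*dy+dz*dz);
                if (dc - rad[t] > bestD) continue;
                int ia=F(t,0)-1, ib=F(t,1)-1, ic=F(t,2)-1;
                for (int i=0;i<3;++i){a[i]=V(ia,i);b[i]=V(ib,i);c[i]=V(ic,i);}
                closestPointTriangle(p, a, b, c, cp, bary);
                double dd = std::sqrt((p[0]-cp[0])*(p[0]-cp[0]) +
                                      (p[1]-cp[1])*(p[1]-cp[1]) +
                                      (p[2]-cp[2])*(p[2]-cp[2]));
                if (dd < bestD) {
                    bestD = dd; bestT = t;
                    for (int i=0;i<3;++i){bcp[i]=cp[i];bbary[i]=bary[i];}
                }
            }
        }
        D[q] = bestD; TRI[q] = bestT + 1;
        for (int i=0;i<3;++i){CP(q,i)=bcp[i];BARY(q,i)=bbary[i];}
    }
    return List::create(_["points"] = CP, _["distance"] = D,
                        _["triangle"] = TRI, _["bary"] = BARY);
}
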