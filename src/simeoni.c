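/* Simeoni tumor-growth-inhibition ODE system, compiled for deSolve.
 *
 * States: x1 proliferating tumor mass, x2..x4 damage-chain stages [cm3].
 * Total burden w = x1 + x2 + x3 + x4.
 *
 *   dx1/dt = lambda0 * x1 / (1 + (lambda0/lambda1 * w)^psi)^(1/psi) - k2*c(t)*x1
 *   dx2/dt = k2*c(t)*x1 - k1*x2
 *   dx3/dt = k1*(x2 - x3)
 *   dx4/dt = k1*(x3 - x4)
 *
 * c(t) enters as a deSolve forcing function (linear interpolation of the
 * supplied concentration grid).
 */
#include <R.h>
#include <math.h>

static double parms[5];
static double forcs[1];

#define lambda0 parms[0]
#define lambda1 parms[1]
#define k1      parms[2]
#define k2      parms[3]
#define psi     parms[4]

#define conc    forcs[0]

void simeoni_init(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms);
}

void simeoni_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forcs);
}

/* Growth function lambda0*x1 / (1 + u^psi)^(1/psi), u = lambda0*w/lambda1,
 * evaluated in a form that cannot overflow for large u^psi:
 * for u > 1, (1 + u^psi)^(1/psi) = u * (1 + u^-psi)^(1/psi). */
static double growth_rate(double x1, double w)
{
    double u = lambda0 * w / lambda1;
    double denom;
    if (u <= 0.0) return lambda0 * x1;
    if (u > 1.0)
        denom = u * pow(1.0 + pow(u, -psi), 1.0 / psi);
    else
        denom = pow(1.0 + pow(u, psi), 1.0 / psi);
    return lambda0 * x1 / denom;
}

void simeoni_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double w = y[0] + y[1] + y[2] + y[3];
    double kill = k2 * conc * y[0];
    ydot[0] = growth_rate(y[0], w) - kill;
    ydot[1] = kill - k1 * y[1];
    ydot[2] = k1 * (y[1] - y[2]);
    ydot[3] = k1 * (y[2] - y[3]);
}
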